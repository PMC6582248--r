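# Nei-Gojobori (1986) Ka/Ks estimation for pairs of aligned, in-frame coding
# sequences. Sites are counted fractionally per codon (a position contributes
# its fraction of synonymous single-nucleotide changes, mutations to stop
# codons counting as nonsynonymous); differences between codons differing at
# k positions are averaged over the k! mutational pathways, excluding
# pathways that pass through a stop codon; proportions are corrected for
# multiple hits with the Jukes-Cantor formula.

NUCLEOTIDES <- c("A", "C", "G", "T")

# permutations of 1..k for k = 1, 2, 3
PATH_ORDERS <- list(
  list(1L),
  list(c(1L, 2L), c(2L, 1L)),
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' The standard genetic code
#'
#' The standard (NCBI transl_table 1) genetic code as a named character
#' vector mapping DNA codons to one-letter amino acids, `*` for stop; taken
#' from [Biostrings::GENETIC_CODE]. Any same-shaped table can be passed to
#' the `code` argument of the Ka/Ks functions.
#'
#' @return A named character vector of length 64.
#' @export
standard_genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  setNames(as.character(code), names(code))
}

validate_code <- function(code) {
  if (is.null(names(code)) || length(code) != 64L ||
      anyDuplicated(names(code)) || !all(nchar(names(code)) == 3L)) {
    abort("A genetic code must be a named character vector over all 64 codons.",
          class = "triadlens_validation_error")
  }
  code
}

assert_sense_codon <- function(codon, code) {
  aa <- code[codon]
  bad <- is.na(aa) | aa == "*"
  if (any(bad)) {
    abort(
      paste0("Not a sense codon: ", paste(unique(codon[bad]), collapse = ", ")),
      class = "triadlens_validation_error"
    )
  }
  invisible(TRUE)
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Each codon position contributes `(# synonymous single-nucleotide
#' changes at that position) / 3` synonymous sites; changes that create a
#' stop codon count as nonsynonymous. `s + n = 3` for every sense codon.
#'
#' @param codon Character vector of sense codons (e.g. `"GGG"`).
#' @param code Genetic code table (see [standard_genetic_code()]).
#' @return A tibble with one row per codon: `codon`, `s`, `n`.
#' @examples
#' codon_sites(c("GGG", "ATG", "AAA"))
#' @export
codon_sites <- function(codon, code = standard_genetic_code()) {
  code <- validate_code(code)
  codon <- toupper(codon)
  assert_sense_codon(codon, code)
  s <- vapply(codon, function(cd) {
    aa <- code[[cd]]
    nt <- strsplit(cd, "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      for (alt in setdiff(NUCLEOTIDES, nt[pos])) {
        mut <- nt
        mut[pos] <- alt
        mut_aa <- code[[paste(mut, collapse = "")]]
        if (mut_aa != "*" && mut_aa == aa) syn <- syn + 1
      }
    }
    syn / 3
  }, numeric(1), USE.NAMES = FALSE)
  tibble(codon = codon, s = s, n = 3 - s)
}

#' Pathway-averaged differences between two codons
#'
#' For codons differing at k positions, averages the synonymous /
#' nonsynonymous step counts over all k! orderings of the single-nucleotide
#' changes. Pathways passing through a stop codon are excluded; if every
#' pathway is blocked, all pathways are used with equal weight (steps into or
#' out of a stop counted as nonsynonymous) and a warning is issued.
#' `sd + nd = k` whenever no pathway is excluded.
#'
#' @param codon1,codon2 Character vectors of sense codons (recycled
#'   pairwise).
#' @param code Genetic code table.
#' @return A tibble with one row per pair: `codon1`, `codon2`, `sd`, `nd`.
#' @examples
#' codon_differences("TTT", "GTA")
#' @export
codon_differences <- function(codon1, codon2, code = standard_genetic_code()) {
  code <- validate_code(code)
  codon1 <- toupper(codon1)
  codon2 <- toupper(codon2)
  assert_sense_codon(c(codon1, codon2), code)
  res <- purrr::map2(codon1, codon2, \(c1, c2) codon_diff_one(c1, c2, code))
  tibble(
    codon1 = codon1, codon2 = codon2,
    sd = purrr::map_dbl(res, 1L), nd = purrr::map_dbl(res, 2L)
  )
}

codon_diff_one <- function(c1, c2, code) {
  nt1 <- strsplit(c1, "")[[1]]
  nt2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(nt1 != nt2)
  k <- length(diff_pos)
  if (k == 0L) {
    return(c(0, 0))
  }
  paths <- lapply(PATH_ORDERS[[k]], function(ord) {
    cur <- nt1
    sd <- 0
    nd <- 0
    blocked <- FALSE
    for (pos in diff_pos[ord]) {
      aa_from <- code[[paste(cur, collapse = "")]]
      cur[pos] <- nt2[pos]
      aa_to <- code[[paste(cur, collapse = "")]]
      if (aa_to == "*" || aa_from == "*") {
        blocked <- TRUE
        nd <- nd + 1
      } else if (aa_from == aa_to) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  open <- !vapply(paths, `[[`, logical(1), "blocked")
  if (!any(open)) {
    warn(paste0("All mutational pathways between ", c1, " and ", c2,
                " pass through a stop codon; averaging over all pathways."))
    open <- rep(TRUE, length(paths))
  }
  used <- paths[open]
  c(
    mean(vapply(used, `[[`, numeric(1), "sd")),
    mean(vapply(used, `[[`, numeric(1), "nd"))
  )
}

#' Jukes-Cantor correction for multiple hits
#'
#' `d = -(3/4) * log(1 - (4/3) p)`. Proportions at or beyond the 3/4
#' saturation boundary have no finite corrected distance and return `NA`.
#'
#' @param p Proportion(s) of differing sites, in `[0, 1]`.
#' @return Corrected distance(s); `NA` where `p >= 3/4` (saturated).
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("Proportions must lie in [0, 1].",
          class = "triadlens_validation_error")
  }
  ifelse(p < 0.75, -0.75 * log1p(-4 * p / 3), NA_real_)
}

# Cached lookup tables (per genetic code): per-codon fractional synonymous
# sites and 64 x 64 pathway-averaged difference matrices.
.ng_cache <- new.env(parent = emptyenv())

ng_tables <- function(code) {
  key <- paste(names(code), code, sep = "=", collapse = ";")
  hit <- .ng_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  sense <- names(code)[code != "*"]
  s_tab <- setNames(codon_sites(sense, code)$s, sense)
  nn <- length(sense)
  SD <- ND <- matrix(NA_real_, nn, nn, dimnames = list(sense, sense))
  for (i in seq_len(nn)) {
    for (j in i:nn) {
      dd <- codon_diff_one(sense[i], sense[j], code)
      SD[i, j] <- SD[j, i] <- dd[1]
      ND[i, j] <- ND[j, i] <- dd[2]
    }
  }
  tabs <- list(s = s_tab, SD = SD, ND = ND, sense = sense)
  .ng_cache[[key]] <- tabs
  tabs
}

split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Nei-Gojobori Ka/Ks for one aligned sequence pair
#'
#' Estimates synonymous (`Ks`) and nonsynonymous (`Ka`) substitution rates
#' for a pair of equal-length, in-frame, aligned coding sequences by the
#' NG86 counting method. Site totals `S` and `N` are averaged across the two
#' sequences; differences are summed over codon pairs with pathway
#' averaging; both proportions are Jukes-Cantor corrected. Codons containing
#' gaps or ambiguity characters in either sequence are skipped pairwise.
#' Internal stop codons are a validation error.
#'
#' The ratio is `Ka/Ks`, reported as 0 when `Ka = 0` with `Ks > 0` (strong
#' purifying selection), and as `NA` (undefined) when `Ks = 0` or either
#' proportion is saturated.
#'
#' @param seq1,seq2 Nucleotide strings (or objects coercible to character) of
#'   equal length divisible by 3.
#' @param code Genetic code table.
#' @param pair_id Optional identifier carried into the result.
#' @return An `ng86` object with elements `S`, `N`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ka`, `Ks`, `ratio`, `flags` (`saturated_s`, `saturated_n`, `zero_ks`),
#'   `n_codons` (compared), `n_skipped`, `pair_id`. See [tidy.ng86()].
#' @examples
#' ng86("GGGAAA", "GGAAAA")
#' @export
ng86 <- function(seq1, seq2, code = standard_genetic_code(), pair_id = NULL) {
  code <- validate_code(code)
  seq1 <- toupper(as.character(seq1))
  seq2 <- toupper(as.character(seq2))
  if (nchar(seq1) != nchar(seq2)) {
    abort("Aligned sequences must have equal length.",
          class = "triadlens_validation_error")
  }
  if (nchar(seq1) == 0L || nchar(seq1) %% 3L != 0L) {
    abort("Sequence length must be a positive multiple of 3.",
          class = "triadlens_validation_error")
  }
  c1 <- split_codons(seq1)
  c2 <- split_codons(seq2)

  clean <- grepl("^[ACGT]{3}$", c1) & grepl("^[ACGT]{3}$", c2)
  stops <- clean & (code[c1] == "*" | code[c2] == "*")
  if (any(stops)) {
    abort(
      paste0("Internal stop codon at codon position ",
             paste(head(which(stops), 5L), collapse = ", ")),
      class = "triadlens_validation_error"
    )
  }
  c1 <- c1[clean]
  c2 <- c2[clean]
  n_codons <- length(c1)
  if (n_codons == 0L) {
    abort("No comparable codons after skipping gaps/ambiguities.",
          class = "triadlens_validation_error")
  }
  tabs <- ng_tables(code)
  S <- (sum(tabs$s[c1]) + sum(tabs$s[c2])) / 2
  N <- 3 * n_codons - S
  idx <- cbind(c1, c2)
  Sd <- sum(tabs$SD[idx])
  Nd <- sum(tabs$ND[idx])
  pS <- Sd / S
  pN <- Nd / N
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  flags <- c(
    saturated_s = is.na(Ks),
    saturated_n = is.na(Ka),
    zero_ks = !is.na(Ks) && Ks == 0
  )
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  structure(
    list(
      pair_id = pair_id %||% NA_character_,
      S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
      Ka = Ka, Ks = Ks, ratio = ratio, flags = flags,
      n_codons = n_codons, n_skipped = sum(!clean)
    ),
    class = "ng86"
  )
}

#' @export
print.ng86 <- function(x, ...) {
  cat("Nei-Gojobori (NG86) pairwise Ka/Ks\n")
  cat(sprintf("  %d codons compared (%d skipped)\n", x$n_codons, x$n_skipped))
  cat(sprintf("  S = %.2f, N = %.2f, Sd = %.2f, Nd = %.2f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  Ka = %s, Ks = %s, Ka/Ks = %s\n",
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$ratio, digits = 4)))
  if (any(x$flags)) {
    cat("  flags:", paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an NG86 result
#'
#' @param x An `ng86` object.
#' @param ... Unused.
#' @return A one-row tibble with the site and difference counts, proportions,
#'   corrected rates, ratio and flags.
#' @export
tidy.ng86 <- function(x, ...) {
  tibble(
    pair_id = x$pair_id,
    n_codons = x$n_codons, S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd,
    pS = x$pS, pN = x$pN, Ka = x$Ka, Ks = x$Ks, ratio = x$ratio,
    saturated_s = unname(x$flags["saturated_s"]),
    saturated_n = unname(x$flags["saturated_n"]),
    zero_ks = unname(x$flags["zero_ks"])
  )
}

#' @rdname tidy.ng86
#' @return For `glance()`: a one-row tibble with `Ka`, `Ks`, `ratio`,
#'   `n_codons` and whether any flag is set.
#' @export
glance.ng86 <- function(x, ...) {
  tibble(
    Ka = x$Ka, Ks = x$Ks, ratio = x$ratio,
    n_codons = x$n_codons, flagged = any(x$flags)
  )
}

#' Ka/Ks for a batch of sequence pairs
#'
#' Runs [ng86()] over every pair named in a pairing manifest against a FASTA
#' file (or named sequence vector).
#'
#' @param sequences FASTA path, [Biostrings::DNAStringSet], or named
#'   character vector of aligned coding sequences.
#' @param pairs Manifest: a data frame (or TSV path) with columns `pair_id`,
#'   `id1`, `id2` and optionally `group`.
#' @param code Genetic code table.
#' @return A tibble with one row per pair (columns of [tidy.ng86()] plus
#'   `group`).
#' @export
pair_kaks_table <- function(pairs, sequences, code = standard_genetic_code()) {
  if (is.character(sequences) && length(sequences) == 1L && is.null(names(sequences))) {
    sequences <- Biostrings::readDNAStringSet(assert_file_exists(sequences))
  }
  seqs <- setNames(as.character(sequences), names(sequences))
  if (is.character(pairs) && length(pairs) == 1L) {
    pairs <- readr::read_tsv(
      assert_file_exists(pairs),
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }
  pairs <- as_tibble(pairs)
  required <- c("pair_id", "id1", "id2")
  if (!all(required %in% names(pairs))) {
    abort("Pair manifest needs columns pair_id, id1, id2.",
          class = "triadlens_format_error")
  }
  if (!"group" %in% names(pairs)) {
    pairs$group <- NA_character_
  }
  if (nrow(pairs) == 0L) {
    return(tibble(
      pair_id = character(), group = character(), n_codons = integer(),
      S = numeric(), N = numeric(), Sd = numeric(), Nd = numeric(),
      pS = numeric(), pN = numeric(), Ka = numeric(), Ks = numeric(),
      ratio = numeric(), saturated_s = logical(), saturated_n = logical(),
      zero_ks = logical()
    ))
  }
  unknown <- setdiff(c(pairs$id1, pairs$id2), names(seqs))
  if (length(unknown) > 0L) {
    abort(
      paste0("Manifest IDs absent from the sequence set: ",
             paste(unique(unknown), collapse = ", ")),
      class = "triadlens_manifest_error"
    )
  }
  purrr::pmap(
    pairs[c("pair_id", "id1", "id2", "group")],
    function(pair_id, id1, id2, group) {
      res <- tidy.ng86(ng86(seqs[[id1]], seqs[[id2]], code, pair_id = pair_id))
      mutate(res, group = group, .after = "pair_id")
    }
  ) |> bind_rows()
}

#' Per-group mean Ka/Ks ratios
#'
#' Averages the Ka/Ks ratio within each group of a [pair_kaks_table()]
#' result. Undefined ratios (saturated, or `Ks = 0`) are excluded from the
#' mean; the number used is reported.
#'
#' @param kaks A [pair_kaks_table()] tibble.
#' @return A tibble: `group`, `n_pairs`, `n_used`, `mean_ratio`.
#' @export
group_mean_kaks <- function(kaks) {
  kaks |>
    group_by(.data$group) |>
    summarise(
      n_pairs = n(),
      n_used = sum(!is.na(.data$ratio)),
      mean_ratio = if (any(!is.na(.data$ratio))) {
        mean(.data$ratio, na.rm = TRUE)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}
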