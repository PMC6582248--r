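#' Read and validate a homoeolog gene roster
#'
#' A roster lists one gene copy (homoeolog) per row, with its triad identifier
#' (`gene_name`), subgenome of origin (A/B/D), physical chromosome (`1A`-`7D`),
#' chromosome arm (S/L, or `.` when unknown), 1-based inclusive coordinates and
#' a phylogenetic group label. The file is UTF-8, tab-separated, with the
#' header `homoeolog_id, gene_name, subgenome, chromosome, arm, start_bp,
#' end_bp, group_label`; `.` marks a missing arm or group.
#'
#' By default a row whose chromosome letter disagrees with its subgenome is a
#' validation error, which catches ordinary data-entry mistakes. Genes caught
#' in an inter-subgenome translocation genuinely live on a chromosome of
#' another subgenome, however (in wheat, the 7BS segment resident on 4AL), so
#' `on_mismatch = "flag"` keeps such rows and marks them `translocated = TRUE`
#' for the rearrangement module to interpret.
#'
#' @param path Path to a roster TSV.
#' @param on_mismatch `"error"` (default) to reject rows whose chromosome
#'   letter differs from their subgenome; `"flag"` to keep them, marked in the
#'   `translocated` column.
#' @return A tibble with one row per homoeolog and columns `homoeolog_id`,
#'   `gene_name`, `subgenome`, `chromosome`, `arm` (`NA` when unknown),
#'   `start_bp`, `end_bp`, `group_label`, `translocated`.
#' @examples
#' roster <- read_roster(triadlens_fixture("table3_roster.tsv"),
#'                       on_mismatch = "flag")
#' nrow(roster)
#' @export
read_roster <- function(path, on_mismatch = c("error", "flag")) {
  on_mismatch <- match.arg(on_mismatch)
  assert_file_exists(path)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  required <- c(
    "homoeolog_id", "gene_name", "subgenome", "chromosome",
    "arm", "start_bp", "end_bp", "group_label"
  )
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    abort(
      paste0(
        "Roster is missing required column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "triadlens_format_error"
    )
  }
  validate_roster(raw[required], on_mismatch = on_mismatch)
}

#' Validate a roster data frame
#'
#' Applies the row-level checks [read_roster()] performs, to an in-memory data
#' frame (e.g. one produced by [simulate_triad_expression()] or assembled by
#' hand). Diagnostics name the offending row numbers.
#'
#' @param roster A data frame with the roster columns (see [read_roster()]).
#' @inheritParams read_roster
#' @return The validated roster as a tibble, with typed coordinate columns,
#'   `NA` arms for `.`/unknown, and a logical `translocated` column.
#' @export
validate_roster <- function(roster, on_mismatch = c("error", "flag")) {
  on_mismatch <- match.arg(on_mismatch)
  roster <- as_tibble(roster)
  fail <- function(rows, why) {
    abort(
      paste0(why, " (row ", paste(rows, collapse = ", "), ")."),
      class = "triadlens_validation_error"
    )
  }

  bad <- which(!roster$subgenome %in% SUBGENOMES)
  if (length(bad)) fail(bad, "subgenome must be one of A, B, D")
  bad <- which(!grepl("^[1-7][ABD]$", roster$chromosome))
  if (length(bad)) fail(bad, "chromosome must match [1-7][ABD]")

  arm <- as.character(roster$arm)
  arm[arm %in% c(".", "", "unknown", NA)] <- NA_character_
  bad <- which(!(is.na(arm) | arm %in% c("S", "L")))
  if (length(bad)) fail(bad, "arm must be S, L or \".\"")

  start_bp <- suppressWarnings(as.numeric(roster$start_bp))
  end_bp <- suppressWarnings(as.numeric(roster$end_bp))
  bad <- which(is.na(start_bp) | is.na(end_bp) | start_bp < 1 | end_bp < start_bp)
  if (length(bad)) fail(bad, "coordinates must satisfy 1 <= start_bp <= end_bp")

  dup <- which(duplicated(roster$homoeolog_id))
  if (length(dup)) {
    fail(dup, paste0(
      "duplicate homoeolog_id: ",
      paste(unique(roster$homoeolog_id[dup]), collapse = ", ")
    ))
  }

  chrom_letter <- substr(roster$chromosome, 2L, 2L)
  mismatch <- which(chrom_letter != roster$subgenome)
  if (length(mismatch) && on_mismatch == "error") {
    fail(mismatch, paste0(
      "chromosome letter disagrees with subgenome for ",
      paste(roster$homoeolog_id[mismatch], collapse = ", "),
      "; a real translocated copy can be kept with on_mismatch = \"flag\""
    ))
  }

  tibble(
    homoeolog_id = as.character(roster$homoeolog_id),
    gene_name = as.character(roster$gene_name),
    subgenome = as.character(roster$subgenome),
    chromosome = as.character(roster$chromosome),
    arm = arm,
    start_bp = start_bp,
    end_bp = end_bp,
    group_label = as.character(roster$group_label),
    translocated = seq_len(nrow(roster)) %in% mismatch
  )
}

#' Assemble homoeolog triads from a roster
#'
#' Groups roster rows by `gene_name` into triads: in hexaploid wheat every
#' gene potentially owns one homoeolog on each of the A, B and D subgenomes.
#' A "triad" here may be incomplete (1 or 2 members), as happens when copies
#' were lost or never annotated.
#'
#' @param roster A validated roster tibble (from [read_roster()] or
#'   [validate_roster()]).
#' @return A tibble ordered by `gene_name`, one row per gene, with columns
#'   `gene_name`, `n_members`, `pattern` (subgenome composition, e.g. `"ABD"`,
#'   `"AD"`, `"B"`) and a `members` list-column holding each gene's roster
#'   rows.
#' @examples
#' roster <- read_roster(triadlens_fixture("table1_roster.tsv"))
#' triads <- assemble_triads(roster)
#' dplyr::count(triads, pattern)
#' @export
assemble_triads <- function(roster) {
  roster <- as_tibble(roster)
  dup <- roster |>
    count(.data$gene_name, .data$subgenome) |>
    filter(n > 1L)
  if (nrow(dup) > 0L) {
    abort(
      paste0(
        "Two homoeologs share a gene_name and subgenome: ",
        paste(paste0(dup$gene_name, "/", dup$subgenome), collapse = ", ")
      ),
      class = "triadlens_validation_error"
    )
  }
  roster |>
    tidyr::nest(members = -"gene_name") |>
    mutate(
      n_members = purrr::map_int(.data$members, nrow),
      pattern = purrr::map_chr(.data$members, \(m) subgenome_pattern(m$subgenome))
    ) |>
    select("gene_name", "n_members", "pattern", "members") |>
    arrange(.data$gene_name)
}

#' Summarise the subgenome distribution of triads
#'
#' Counts triads by subgenome composition pattern (ABD, AB, AD, BD, A, B, D)
#' and reports the bookkeeping totals: number of genes, number of homoeologs
#' (3 per complete triad, 2 per two-member gene, 1 per singleton) and the
#' fraction of genes with all three homoeologs.
#'
#' @param triads A triad tibble from [assemble_triads()].
#' @return An object of class `triad_distribution`; see [tidy.triad_distribution()]
#'   for the per-pattern counts and [glance.triad_distribution()] for totals.
#' @examples
#' read_roster(triadlens_fixture("table1_roster.tsv")) |>
#'   assemble_triads() |>
#'   distribution_summary()
#' @export
distribution_summary <- function(triads) {
  if (nrow(triads) == 0L) {
    abort("No triads supplied.", class = "triadlens_empty_input_error")
  }
  counts <- setNames(integer(length(DISTRIBUTION_PATTERNS)), DISTRIBUTION_PATTERNS)
  tab <- table(triads$pattern)
  counts[names(tab)] <- as.integer(tab)
  total_genes <- sum(counts)
  total_homoeologs <- sum(counts * nchar(DISTRIBUTION_PATTERNS))
  structure(
    list(
      counts = counts,
      total_genes = total_genes,
      total_homoeologs = total_homoeologs,
      fraction_complete = counts[["ABD"]] / total_genes
    ),
    class = "triad_distribution"
  )
}

#' @export
print.triad_distribution <- function(x, ...) {
  cat("Subgenome distribution of homoeolog triads\n")
  cat(sprintf(
    "  %d homoeologs across %d genes; %.1f%% complete (A+B+D) triads\n",
    x$total_homoeologs, x$total_genes, 100 * x$fraction_complete
  ))
  for (p in DISTRIBUTION_PATTERNS) {
    cat(sprintf("  %-3s %4d\n", p, x$counts[[p]]))
  }
  invisible(x)
}

#' Tidy a triad distribution summary
#'
#' @param x A `triad_distribution` object.
#' @param ... Unused.
#' @return A tibble with columns `pattern`, `n_genes`, `n_homoeologs`.
#' @export
tidy.triad_distribution <- function(x, ...) {
  tibble(
    pattern = DISTRIBUTION_PATTERNS,
    n_genes = as.integer(x$counts[DISTRIBUTION_PATTERNS]),
    n_homoeologs = as.integer(
      x$counts[DISTRIBUTION_PATTERNS] * nchar(DISTRIBUTION_PATTERNS)
    )
  )
}

#' One-row totals for a triad distribution summary
#'
#' @param x A `triad_distribution` object.
#' @param ... Unused.
#' @return A one-row tibble: `total_genes`, `total_homoeologs`,
#'   `fraction_complete`.
#' @export
glance.triad_distribution <- function(x, ...) {
  tibble(
    total_genes = x$total_genes,
    total_homoeologs = x$total_homoeologs,
    fraction_complete = x$fraction_complete
  )
}
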