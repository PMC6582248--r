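# Synthetic-data generators. These define the statistical world the rest of
# the package is tested in: triad TPM triplets drawn around the seven bias
# centroids (Dirichlet noise, log-normal depth), condition pairs with
# controlled category transitions, and codon-aligned sequence pairs evolved
# under a stated omega. Every generator is deterministic given its seed and
# returns the ground truth alongside the data.

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Dirichlet parameters concentrated around a category centroid. Suppressed
# and dominant centroids sit on the simplex boundary, so a small epsilon is
# mixed in before scaling to keep every parameter positive.
centroid_alpha <- function(category, concentration, eps = 1e-3) {
  cen <- bias_centroids(as_matrix = TRUE)[category, ]
  concentration * (cen + eps) / (1 + 3 * eps)
}

validate_mix <- function(category_mix) {
  if (is.null(category_mix)) {
    # Study-like default: roughly one third of triads biased, spread evenly
    # over the six unbalanced categories.
    category_mix <- setNames(c(2 / 3, rep(1 / 18, 6)), BIAS_CATEGORIES)
  }
  if (is.null(names(category_mix)) ||
      !setequal(names(category_mix), BIAS_CATEGORIES) ||
      any(category_mix < 0) ||
      abs(sum(category_mix) - 1) > 1e-9) {
    abort(
      "category_mix must be a non-negative probability vector named by the seven bias categories, summing to 1.",
      class = "triadlens_configuration_error"
    )
  }
  category_mix[BIAS_CATEGORIES]
}

sim_expression_rows <- function(genes, categories, concentration,
                                depth_log_mean, depth_log_sd) {
  rel <- t(vapply(
    categories,
    \(cat) rdirichlet_one(centroid_alpha(cat, concentration)),
    numeric(3)
  ))
  total <- rlnorm(length(genes), depth_log_mean, depth_log_sd)
  tibble(
    gene_name = genes,
    category = factor(categories, levels = BIAS_CATEGORIES),
    r_A = rel[, 1], r_B = rel[, 2], r_D = rel[, 3],
    total_tpm = total,
    tpm_A = total * rel[, 1], tpm_B = total * rel[, 2], tpm_D = total * rel[, 3]
  )
}

truth_to_expr <- function(truth, condition, missing_rate) {
  expr <- tibble(
    homoeolog_id = as.vector(rbind(
      paste0(truth$gene_name, "-A"),
      paste0(truth$gene_name, "-B"),
      paste0(truth$gene_name, "-D")
    )),
    tpm = as.vector(rbind(truth$tpm_A, truth$tpm_B, truth$tpm_D))
  )
  if (missing_rate > 0) {
    expr <- expr[runif(nrow(expr)) >= missing_rate, ]
  }
  names(expr)[2] <- condition
  expr
}

#' Simulate triad expression with known bias structure
#'
#' Draws, for each simulated triad, a bias category from `category_mix`,
#' relative homoeolog abundances from a Dirichlet distribution concentrated
#' at that category's centroid, and a total triad TPM from a log-normal
#' depth model; homoeolog TPM is the product. Homoeolog rows are then dropped
#' independently with probability `missing_rate`, emulating the blank cells
#' of real expression compendia. The generated matrix, roster and metadata
#' are in exactly the shapes the analysis functions consume, and the truth
#' table records every latent quantity.
#'
#' @param n_triads Number of triads (default 76, a complete-triad census at
#'   the scale of a large gene family).
#' @param category_mix Named probability vector over the seven categories;
#'   the default puts 2/3 of triads in `Balanced` and spreads the rest evenly
#'   (about one third of triads biased).
#' @param concentration Dirichlet concentration about the centroid (default
#'   200; larger = tighter).
#' @param depth_log_mean,depth_log_sd Log-normal parameters of total triad
#'   TPM (defaults `log(10)` and 1).
#' @param missing_rate Probability each homoeolog row is absent (default 0).
#' @param condition Condition label for the single generated sample.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list: `expr` (tibble `homoeolog_id` + one TPM column), `roster`
#'   (validated roster for the simulated genes), `meta` (one-row sample
#'   sheet), `truth` (per-triad category, relative abundances, depth), and
#'   `params` (the generator settings, reused by [simulate_stress_shift()]).
#' @examples
#' sim <- simulate_triad_expression(n_triads = 10, seed = 1)
#' sim$truth
#' @export
simulate_triad_expression <- function(n_triads = 76,
                                      category_mix = NULL,
                                      concentration = 200,
                                      depth_log_mean = log(10),
                                      depth_log_sd = 1,
                                      missing_rate = 0,
                                      condition = "control",
                                      seed = NULL) {
  stopifnot(n_triads >= 1, depth_log_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (concentration <= 0) {
    abort("concentration must be positive.",
          class = "triadlens_configuration_error")
  }
  category_mix <- validate_mix(category_mix)
  genes <- sprintf("sim%04d", seq_len(n_triads))

  with_seed(seed, {
    categories <- sample(BIAS_CATEGORIES, n_triads, replace = TRUE,
                         prob = category_mix)
    truth <- sim_expression_rows(genes, categories, concentration,
                                 depth_log_mean, depth_log_sd)
    truth$condition <- condition
    expr <- truth_to_expr(truth, condition, missing_rate)

    chrom_num <- 1L + (seq_len(n_triads) - 1L) %% 7L
    roster <- validate_roster(tibble(
      homoeolog_id = as.vector(rbind(
        paste0(genes, "-A"), paste0(genes, "-B"), paste0(genes, "-D")
      )),
      gene_name = rep(genes, each = 3),
      subgenome = rep(SUBGENOMES, n_triads),
      chromosome = paste0(rep(chrom_num, each = 3), rep(SUBGENOMES, n_triads)),
      arm = "L",
      start_bp = rep(1e5 * seq_len(n_triads), each = 3),
      end_bp = rep(1e5 * seq_len(n_triads), each = 3) + 3000,
      group_label = "ungrouped"
    ))

    list(
      expr = expr,
      roster = roster,
      meta = tibble(sample_id = condition, tissue = "leaf",
                    stage = "seedling", condition = condition,
                    replicate = "1"),
      truth = truth,
      params = list(
        n_triads = n_triads, category_mix = category_mix,
        concentration = concentration, depth_log_mean = depth_log_mean,
        depth_log_sd = depth_log_sd, missing_rate = missing_rate,
        condition = condition, seed = seed
      )
    )
  })
}

#' Default category-transition matrix for a stress condition
#'
#' A mild, row-stochastic 7 x 7 transition matrix emulating the qualitative
#' behaviour of triads under abiotic stress: most triads keep their
#' category, and balanced triads that move shift predominantly into D- and
#' B-homoeolog dominance.
#'
#' @return A 7 x 7 row-stochastic matrix with category dimnames.
#' @export
default_stress_transitions <- function() {
  m <- diag(0.80, 7)
  dimnames(m) <- list(BIAS_CATEGORIES, BIAS_CATEGORIES)
  m["Balanced", ] <- c(0.70, 0.02, 0.08, 0.12, 0.04, 0.02, 0.02)
  for (cat in BIAS_CATEGORIES[-1]) {
    m[cat, "Balanced"] <- 0.10
    rest <- setdiff(BIAS_CATEGORIES, c(cat, "Balanced"))
    m[cat, rest] <- 0.10 / length(rest)
  }
  m
}

#' Simulate a second condition with controlled category shifts
#'
#' Given a [simulate_triad_expression()] result, draws each triad's
#' second-condition category from the corresponding row of a transition
#' matrix and regenerates expression under the same noise model, yielding a
#' condition-paired matrix with known transition structure.
#'
#' @param sim A [simulate_triad_expression()] result.
#' @param transitions 7 x 7 row-stochastic matrix (rows and columns in
#'   category order); default [default_stress_transitions()].
#' @param condition Label for the new condition (default `"stress"`).
#' @param seed Integer seed.
#' @return A list like [simulate_triad_expression()]'s (`expr`, `meta`,
#'   `truth`, `params`), for the new condition; the roster is unchanged and
#'   not repeated.
#' @export
simulate_stress_shift <- function(sim, transitions = default_stress_transitions(),
                                  condition = "stress", seed = NULL) {
  transitions <- as.matrix(transitions)
  if (!all(dim(transitions) == c(7L, 7L)) || any(transitions < 0) ||
      any(abs(rowSums(transitions) - 1) > 1e-9)) {
    abort("transitions must be a non-negative row-stochastic 7 x 7 matrix.",
          class = "triadlens_validation_error")
  }
  if (is.null(dimnames(transitions))) {
    dimnames(transitions) <- list(BIAS_CATEGORIES, BIAS_CATEGORIES)
  } else if (!identical(rownames(transitions), BIAS_CATEGORIES)) {
    transitions <- transitions[BIAS_CATEGORIES, BIAS_CATEGORIES]
  }
  p <- sim$params
  base_cat <- as.character(sim$truth$category)

  with_seed(seed, {
    new_cat <- vapply(base_cat, function(cat) {
      sample(BIAS_CATEGORIES, 1L, prob = transitions[cat, ])
    }, character(1), USE.NAMES = FALSE)
    truth <- sim_expression_rows(sim$truth$gene_name, new_cat,
                                 p$concentration, p$depth_log_mean,
                                 p$depth_log_sd)
    truth$condition <- condition
    truth$category_from <- sim$truth$category
    expr <- truth_to_expr(truth, condition, p$missing_rate)
    list(
      expr = expr,
      meta = tibble(sample_id = condition, tissue = "leaf",
                    stage = "seedling", condition = condition,
                    replicate = "1"),
      truth = truth,
      params = c(p[setdiff(names(p), c("condition", "seed"))],
                 list(condition = condition, seed = seed,
                      transitions = transitions))
    )
  })
}

#' Simulate an aligned codon sequence pair under a known omega
#'
#' Draws a random sense-codon ancestor and evolves two descendant copies
#' independently: single-nucleotide codon changes are proposed uniformly,
#' changes creating stop codons are rejected, synonymous changes are accepted
#' with relative rate 1 and nonsynonymous changes with relative rate `omega`,
#' until a Poisson(`expected_subs_per_codon * n_codons`) number of accepted
#' substitutions has occurred on each lineage. The realised substitution
#' counts are returned as truth.
#'
#' @param n_codons Alignment length in codons.
#' @param omega Nonsynonymous/synonymous rate ratio (> 0).
#' @param expected_subs_per_codon Expected accepted substitutions per codon
#'   per lineage (branch length `t`).
#' @param seed Integer seed.
#' @param code Genetic code table.
#' @return A list: `seq1`, `seq2` (nucleotide strings), `ancestor`, and
#'   `truth` (omega, t, per-lineage realised synonymous / nonsynonymous
#'   substitution counts).
#' @examples
#' pair <- simulate_codon_pair(n_codons = 100, omega = 0.5,
#'                             expected_subs_per_codon = 0.1, seed = 1)
#' ng86(pair$seq1, pair$seq2)
#' @export
simulate_codon_pair <- function(n_codons = 500, omega = 0.2,
                                expected_subs_per_codon = 0.2,
                                seed = NULL, code = standard_genetic_code()) {
  if (n_codons < 1 || omega <= 0 || expected_subs_per_codon < 0) {
    abort("n_codons, omega must be positive; expected_subs_per_codon >= 0.",
          class = "triadlens_configuration_error")
  }
  code <- validate_code(code)
  sense <- names(code)[code != "*"]
  p_syn <- min(1, 1 / omega)
  p_non <- min(1, omega)

  evolve <- function(codons) {
    target <- rpois(1L, expected_subs_per_codon * length(codons))
    n_syn <- 0L
    n_non <- 0L
    while (n_syn + n_non < target) {
      i <- sample.int(length(codons), 1L)
      cd <- codons[i]
      pos <- sample.int(3L, 1L)
      cur_nt <- substr(cd, pos, pos)
      alt <- sample(setdiff(NUCLEOTIDES, cur_nt), 1L)
      mut <- cd
      substr(mut, pos, pos) <- alt
      if (code[[mut]] == "*") next
      syn <- code[[mut]] == code[[cd]]
      if (runif(1L) < (if (syn) p_syn else p_non)) {
        codons[i] <- mut
        if (syn) n_syn <- n_syn + 1L else n_non <- n_non + 1L
      }
    }
    list(codons = codons, n_syn = n_syn, n_non = n_non)
  }

  with_seed(seed, {
    ancestor <- sample(sense, n_codons, replace = TRUE)
    d1 <- evolve(ancestor)
    d2 <- evolve(ancestor)
    list(
      seq1 = paste(d1$codons, collapse = ""),
      seq2 = paste(d2$codons, collapse = ""),
      ancestor = paste(ancestor, collapse = ""),
      truth = tibble(
        lineage = c(1L, 2L),
        omega = omega,
        t = expected_subs_per_codon,
        n_syn = c(d1$n_syn, d2$n_syn),
        n_nonsyn = c(d1$n_non, d2$n_non)
      )
    )
  })
}

#' Simulate a batch of codon pairs with group labels
#'
#' Convenience wrapper around [simulate_codon_pair()] producing the
#' (sequences, manifest) inputs of [pair_kaks_table()].
#'
#' @param n_pairs Pairs per group.
#' @param omega Vector of omega values, one per group (groups are named
#'   `"omega_<value>"` unless `groups` is given).
#' @param groups Optional group labels, parallel to `omega`.
#' @param n_codons,expected_subs_per_codon Passed to [simulate_codon_pair()].
#' @param seed Integer seed (each pair uses an offset of it).
#' @return A list: `sequences` (named character vector), `pairs` (manifest
#'   tibble with `pair_id`, `id1`, `id2`, `group`), `truth`.
#' @export
simulate_codon_pairs <- function(n_pairs = 5, omega = c(0.2, 0.8),
                                 groups = NULL, n_codons = 500,
                                 expected_subs_per_codon = 0.2, seed = NULL) {
  groups <- groups %||% paste0("omega_", omega)
  stopifnot(length(groups) == length(omega))
  grid <- tidyr::expand_grid(
    group_idx = seq_along(omega),
    rep = seq_len(n_pairs)
  )
  seqs <- character(0)
  rows <- vector("list", nrow(grid))
  truths <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    gi <- grid$group_idx[i]
    pair_seed <- if (is.null(seed)) NULL else seed + i
    pair <- simulate_codon_pair(n_codons, omega[gi], expected_subs_per_codon,
                                seed = pair_seed)
    id1 <- sprintf("p%03d_1", i)
    id2 <- sprintf("p%03d_2", i)
    seqs[id1] <- pair$seq1
    seqs[id2] <- pair$seq2
    rows[[i]] <- tibble(
      pair_id = sprintf("p%03d", i), id1 = id1, id2 = id2,
      group = groups[gi]
    )
    truths[[i]] <- mutate(pair$truth, pair_id = sprintf("p%03d", i),
                          .before = 1L)
  }
  list(
    sequences = seqs,
    pairs = bind_rows(rows),
    truth = bind_rows(truths)
  )
}
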