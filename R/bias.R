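# Homoeolog expression-bias classification. Within a triad, each homoeolog's
# TPM is expressed as its relative contribution to total triad expression, a
# point on the 2-simplex. The simplex is partitioned by nearest-centroid
# assignment to seven canonical points: the balanced 1:1:1 expectation, three
# single-homoeolog dominance corners, and three suppressed patterns where one
# homoeolog is silent and the other two share expression equally.

#' The seven bias-category centroids
#'
#' @param as_matrix Return a 7 x 3 numeric matrix instead of a tibble.
#' @return Centroid coordinates `(r_A, r_B, r_D)` per category: Balanced
#'   (1/3, 1/3, 1/3); `X_dominant` the unit vector of X; `X_suppressed` zero
#'   at X and 1/2 elsewhere.
#' @export
bias_centroids <- function(as_matrix = FALSE) {
  m <- rbind(
    Balanced     = c(1, 1, 1) / 3,
    A_dominant   = c(1, 0, 0),
    B_dominant   = c(0, 1, 0),
    D_dominant   = c(0, 0, 1),
    A_suppressed = c(0, 1, 1) / 2,
    B_suppressed = c(1, 0, 1) / 2,
    D_suppressed = c(1, 1, 0) / 2
  )
  colnames(m) <- c("r_A", "r_B", "r_D")
  if (as_matrix) {
    return(m)
  }
  tibble(category = rownames(m), r_A = m[, 1], r_B = m[, 2], r_D = m[, 3])
}

check_simplex <- function(r_A, r_B, r_D, tolerance = 1e-6, what = "rel") {
  ok <- is.na(r_A) | (
    r_A >= -tolerance & r_B >= -tolerance & r_D >= -tolerance &
      abs(r_A + r_B + r_D - 1) <= tolerance
  )
  if (!all(ok)) {
    abort(
      paste0(what, " must lie on the unit 2-simplex (non-negative, summing to 1; ",
             "tolerance ", format(tolerance), "); offending index ",
             paste(head(which(!ok), 5L), collapse = ", ")),
      class = "triadlens_validation_error"
    )
  }
  invisible(TRUE)
}

#' Relative homoeolog abundance within triads
#'
#' Normalises a triad's (A, B, D) TPM triplet to its relative contributions
#' `r_i = tpm_i / sum(tpm)`. Triads whose summed TPM falls below
#' `min_total_tpm` are called not expressed: their relative abundances (and
#' any downstream category) are undefined, reported as `NA`.
#'
#' @param tpm_A,tpm_B,tpm_D Non-negative TPM vectors, one entry per triad.
#' @param min_total_tpm Minimum summed TPM for a triad to count as expressed
#'   (default 0.5).
#' @return A tibble with columns `expressed`, `r_A`, `r_B`, `r_D`.
#' @examples
#' relative_abundance(c(10, 2, 0), c(10, 1, 0), c(10, 1, 0))
#' @export
relative_abundance <- function(tpm_A, tpm_B, tpm_D, min_total_tpm = 0.5) {
  tpm <- cbind(tpm_A, tpm_B, tpm_D)
  if (any(tpm < 0, na.rm = TRUE)) {
    abort("TPM values must be non-negative.",
          class = "triadlens_validation_error")
  }
  total <- tpm_A + tpm_B + tpm_D
  expressed <- !is.na(total) & total >= min_total_tpm
  rel <- tpm / total
  rel[!expressed, ] <- NA_real_
  tibble(
    expressed = ifelse(is.na(total), NA, expressed),
    r_A = unname(rel[, 1]), r_B = unname(rel[, 2]), r_D = unname(rel[, 3])
  )
}

#' Classify relative abundances into the seven bias categories
#'
#' Assigns each simplex point to the nearest of the seven centroids
#' ([bias_centroids()]) in Euclidean distance. Exact ties are assigned
#' `Balanced` (the conservative call). Optionally, any point within
#' `balanced_radius` of the balanced centroid is called `Balanced` regardless
#' of the nearest centroid; this variant is off by default.
#'
#' @param r_A,r_B,r_D Relative abundance vectors on the simplex (`NA` rows
#'   propagate to `NA` categories).
#' @param tolerance Allowed numerical departure from the simplex (default
#'   1e-6); worse departures are a validation error.
#' @param balanced_radius Optional radius of a forced-Balanced ball around
#'   (1/3, 1/3, 1/3); `NULL` (default) disables it.
#' @return A factor with levels `Balanced`, `A_dominant`, `B_dominant`,
#'   `D_dominant`, `A_suppressed`, `B_suppressed`, `D_suppressed`.
#' @examples
#' classify_bias(c(1/3, 1, 0.05), c(1/3, 0, 0.475), c(1/3, 0, 0.475))
#' @export
classify_bias <- function(r_A, r_B, r_D, tolerance = 1e-6,
                          balanced_radius = NULL) {
  check_simplex(r_A, r_B, r_D, tolerance)
  rel <- cbind(r_A, r_B, r_D)
  cen <- bias_centroids(as_matrix = TRUE)
  # squared Euclidean distance of every point to every centroid
  d2 <- outer(rowSums(rel^2), rowSums(cen^2), "+") - 2 * rel %*% t(cen)
  cat_idx <- apply(d2, 1L, function(d) {
    if (anyNA(d)) {
      return(NA_integer_)
    }
    hits <- which(d <= min(d) + 1e-12)
    if (length(hits) > 1L) 1L else hits
  })
  out <- factor(rownames(cen)[cat_idx], levels = BIAS_CATEGORIES)
  if (!is.null(balanced_radius)) {
    near <- sqrt(rowSums(sweep(rel, 2L, cen["Balanced", ])^2)) <= balanced_radius
    out[which(near)] <- "Balanced"
  }
  out
}

#' Ternary plot coordinates for simplex points
#'
#' Maps relative abundances to the unit-edge triangle with corners
#' A = (0, 0), B = (1, 0), D = (1/2, sqrt(3)/2):
#' `x = r_B + r_D / 2`, `y = sqrt(3)/2 * r_D`. The map is a bijection from
#' the simplex to the triangle; [ternary_to_simplex()] inverts it.
#'
#' @inheritParams classify_bias
#' @return A tibble with columns `x`, `y`.
#' @export
ternary_coordinates <- function(r_A, r_B, r_D, tolerance = 1e-6) {
  check_simplex(r_A, r_B, r_D, tolerance)
  tibble(x = r_B + r_D / 2, y = sqrt(3) / 2 * r_D)
}

#' @rdname ternary_coordinates
#' @param x,y Ternary coordinates in the unit-edge triangle.
#' @export
ternary_to_simplex <- function(x, y) {
  r_D <- 2 * y / sqrt(3)
  r_B <- x - y / sqrt(3)
  tibble(r_A = 1 - r_B - r_D, r_B = r_B, r_D = r_D)
}

#' log2(TPM + 1) transform of an expression table
#'
#' Applies the conventional `log2(TPM + 1)` transform to every numeric column
#' of an expression table; the +1 pseudo-count keeps zeros finite and maps 0
#' to 0. Missing cells stay missing.
#'
#' @param expr An expression tibble (first column `homoeolog_id`, remaining
#'   columns numeric TPM), or a numeric matrix/vector.
#' @return The same shape, transformed.
#' @export
log_transform_tpm <- function(expr) {
  tf <- function(v) {
    if (any(v < 0, na.rm = TRUE)) {
      abort("TPM values must be non-negative.",
            class = "triadlens_validation_error")
    }
    log2(v + 1)
  }
  if (is.numeric(expr)) {
    return(tf(expr))
  }
  expr <- as_tibble(expr)
  num <- vapply(expr, is.numeric, logical(1))
  expr[num] <- lapply(expr[num], tf)
  expr
}

#' Read an expression matrix / sample metadata sheet
#'
#' The expression TSV has `homoeolog_id` as its first column and one numeric
#' TPM column per sample; empty cells or `.` are missing data (distinct from
#' an observed 0). The metadata TSV has columns `sample_id`, `tissue`,
#' `stage`, `condition`, `replicate`, covering every expression column.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_expression <- function(path) {
  assert_file_exists(path)
  expr <- readr::read_tsv(
    path,
    col_types = readr::cols(
      homoeolog_id = readr::col_character(),
      .default = readr::col_double()
    ),
    na = c("", ".", "NA"), progress = FALSE
  )
  if (names(expr)[1] != "homoeolog_id") {
    abort("Expression table must have homoeolog_id as its first column.",
          class = "triadlens_format_error")
  }
  if (anyDuplicated(expr$homoeolog_id)) {
    abort("Duplicate homoeolog_id in expression table.",
          class = "triadlens_validation_error")
  }
  if (any(vapply(expr[-1], function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    abort("TPM values must be non-negative.",
          class = "triadlens_validation_error")
  }
  expr
}

#' @rdname read_expression
#' @export
read_sample_meta <- function(path) {
  assert_file_exists(path)
  meta <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("sample_id", "tissue", "stage", "condition", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    abort(
      paste0("Sample metadata is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "triadlens_format_error"
    )
  }
  meta
}

# Per-gene, per-condition TPM triplets. Replicate samples of a condition are
# aggregated with `agg` (NA propagates: a missing replicate leaves the
# condition missing for that homoeolog). Returns one row per gene x condition
# with tpm_A/tpm_B/tpm_D (NA when the member row is absent or missing) and
# `complete` = all three members present with data.
condition_tpm <- function(expr, roster, meta = NULL, conditions = NULL,
                          agg = c("mean", "median")) {
  agg <- match.arg(agg)
  agg_fun <- if (agg == "mean") mean else stats::median
  expr <- as_tibble(expr)
  sample_cols <- setdiff(names(expr), "homoeolog_id")
  if (is.null(meta)) {
    meta <- tibble(sample_id = sample_cols, condition = sample_cols)
  }
  if (!all(sample_cols %in% meta$sample_id)) {
    abort("Sample metadata does not cover every expression column.",
          class = "triadlens_configuration_error")
  }
  if (is.null(conditions)) {
    conditions <- unique(meta$condition[meta$sample_id %in% sample_cols])
  }
  keep <- meta$sample_id[meta$condition %in% conditions]
  if (length(keep) == 0L) {
    abort(
      paste0("No expression columns for condition(s): ",
             paste(conditions, collapse = ", ")),
      class = "triadlens_configuration_error"
    )
  }

  long <- expr |>
    tidyr::pivot_longer(-"homoeolog_id", names_to = "sample_id",
                        values_to = "tpm") |>
    inner_join(meta[c("sample_id", "condition")], by = "sample_id") |>
    filter(.data$condition %in% conditions) |>
    group_by(.data$homoeolog_id, .data$condition) |>
    summarise(tpm = agg_fun(.data$tpm), .groups = "drop")

  roster |>
    select("homoeolog_id", "gene_name", "subgenome") |>
    inner_join(long, by = "homoeolog_id") |>
    select("gene_name", "subgenome", "condition", "tpm") |>
    tidyr::pivot_wider(names_from = "subgenome", values_from = "tpm",
                       names_prefix = "tpm_") |>
    (\(d) {
      for (col in paste0("tpm_", SUBGENOMES)) {
        if (!col %in% names(d)) d[[col]] <- NA_real_
      }
      d
    })() |>
    mutate(complete = !is.na(.data$tpm_A) & !is.na(.data$tpm_B) & !is.na(.data$tpm_D)) |>
    select("gene_name", "condition", "tpm_A", "tpm_B", "tpm_D", "complete") |>
    arrange(.data$gene_name, .data$condition)
}

#' Select triads complete in an expression matrix
#'
#' Keeps the triads whose three members are all present as expression rows
#' with no missing cell in the chosen conditions — the selection step before
#' any homoeolog-bias analysis (absent rows and missing cells are "no data",
#' unlike observed zeros, which keep the triad).
#'
#' @param expr Expression tibble (see [read_expression()]).
#' @param roster A validated roster tibble.
#' @param meta Optional sample metadata (see [read_sample_meta()]); when
#'   `NULL` each expression column is treated as its own condition.
#' @param conditions Conditions to require data in; default all.
#' @return The [assemble_triads()] tibble restricted to retained triads.
#' @export
select_complete_triads <- function(expr, roster, meta = NULL, conditions = NULL) {
  ct <- condition_tpm(expr, roster, meta, conditions)
  ok <- ct |>
    group_by(.data$gene_name) |>
    summarise(keep = all(.data$complete), .groups = "drop") |>
    filter(.data$keep)
  triads <- assemble_triads(roster)
  triads[triads$gene_name %in% ok$gene_name & triads$pattern == "ABD", ]
}

#' Per-triad homoeolog bias across conditions
#'
#' The central bias pipeline: aggregates replicate samples per condition,
#' keeps triads complete in each condition, computes relative homoeolog
#' abundances, classifies them into the seven bias categories and attaches
#' ternary plot coordinates.
#'
#' @inheritParams select_complete_triads
#' @param min_total_tpm Expression filter passed to [relative_abundance()].
#' @param agg Replicate aggregation: `"mean"` (default) or `"median"`.
#' @param balanced_radius Passed to [classify_bias()].
#' @return A tibble with one row per triad x condition: `gene_name`,
#'   `condition`, `tpm_A/B/D`, `expressed`, `r_A/B/D`, `x`, `y`, `category`.
#'   Triads missing data in a condition are omitted for that condition.
#' @examples
#' sim <- simulate_triad_expression(n_triads = 20, seed = 7)
#' triad_bias(sim$expr, sim$roster)
#' @export
triad_bias <- function(expr, roster, meta = NULL, conditions = NULL,
                       min_total_tpm = 0.5, agg = c("mean", "median"),
                       balanced_radius = NULL) {
  ct <- condition_tpm(expr, roster, meta, conditions, agg) |>
    filter(.data$complete)
  rel <- relative_abundance(ct$tpm_A, ct$tpm_B, ct$tpm_D, min_total_tpm)
  xy <- tibble(x = rep(NA_real_, nrow(ct)), y = NA_real_)
  expressed <- which(rel$expressed)
  if (length(expressed) > 0L) {
    xy[expressed, ] <- ternary_coordinates(
      rel$r_A[expressed], rel$r_B[expressed], rel$r_D[expressed]
    )
  }
  ct |>
    select(-"complete") |>
    mutate(
      expressed = rel$expressed,
      r_A = rel$r_A, r_B = rel$r_B, r_D = rel$r_D,
      x = xy$x, y = xy$y,
      category = classify_bias(rel$r_A, rel$r_B, rel$r_D,
                               balanced_radius = balanced_radius)
    )
}

#' Per-subgenome dominance and suppression tallies
#'
#' @param bias A [triad_bias()] tibble.
#' @return A tibble with one row per condition x subgenome: counts of triads
#'   where that subgenome's homoeolog is dominant or suppressed, plus the
#'   number of balanced and expressed triads in the condition.
#' @export
subgenome_bias_counts <- function(bias) {
  expressed <- filter(bias, .data$expressed)
  purrr::map(unique(expressed$condition), function(cond) {
    b <- filter(expressed, .data$condition == cond)
    tibble(
      condition = cond,
      subgenome = SUBGENOMES,
      n_dominant = vapply(SUBGENOMES, \(s) sum(b$category == paste0(s, "_dominant")),
                          integer(1), USE.NAMES = FALSE),
      n_suppressed = vapply(SUBGENOMES, \(s) sum(b$category == paste0(s, "_suppressed")),
                            integer(1), USE.NAMES = FALSE),
      n_balanced = sum(b$category == "Balanced"),
      n_expressed = nrow(b)
    )
  }) |> bind_rows()
}

#' Category shifts between two conditions
#'
#' Cross-tabulates bias categories of the triads expressed in both of two
#' conditions (e.g. control vs stress) into a 7 x 7 transition matrix, with
#' per-subgenome dominance/suppression tallies for each condition.
#'
#' @param bias_from,bias_to [triad_bias()] tibbles, each holding a single
#'   condition; triads are matched by `gene_name`.
#' @return A `bias_shift` object: `transitions` (7 x 7 count matrix, rows =
#'   first condition), `per_subgenome`, `n_shared`, `conditions`. See
#'   [tidy.bias_shift()].
#' @examples
#' sim <- simulate_triad_expression(n_triads = 30, seed = 1)
#' shifted <- simulate_stress_shift(sim, seed = 2)
#' shift_table(triad_bias(sim$expr, sim$roster),
#'             triad_bias(shifted$expr, sim$roster))
#' @export
shift_table <- function(bias_from, bias_to) {
  for (b in list(bias_from, bias_to)) {
    if (length(unique(b$condition)) > 1L) {
      abort("Each bias table passed to shift_table() must hold one condition.",
            class = "triadlens_validation_error")
    }
    if (anyDuplicated(b$gene_name)) {
      abort("Duplicated gene_name within a condition.",
            class = "triadlens_validation_error")
    }
  }
  joined <- inner_join(
    filter(bias_from, .data$expressed),
    filter(bias_to, .data$expressed),
    by = "gene_name", suffix = c("_from", "_to")
  )
  transitions <- table(
    factor(joined$category_from, levels = BIAS_CATEGORIES),
    factor(joined$category_to, levels = BIAS_CATEGORIES)
  )
  transitions <- unclass(transitions)
  names(dimnames(transitions)) <- NULL
  structure(
    list(
      transitions = transitions,
      per_subgenome = subgenome_bias_counts(bind_rows(bias_from, bias_to)),
      n_shared = nrow(joined),
      conditions = c(unique(bias_from$condition), unique(bias_to$condition))
    ),
    class = "bias_shift"
  )
}

#' @export
print.bias_shift <- function(x, ...) {
  cat(sprintf(
    "Bias-category shifts: %s -> %s (%d triads expressed in both)\n",
    x$conditions[1], x$conditions[2], x$n_shared
  ))
  print(x$transitions)
  invisible(x)
}

#' Tidy a bias-shift table
#'
#' @param x A `bias_shift` object.
#' @param ... Unused.
#' @return A tibble in long form: `from`, `to`, `n`.
#' @export
tidy.bias_shift <- function(x, ...) {
  as_tibble(as.data.frame.table(as.table(x$transitions),
                                stringsAsFactors = FALSE)) |>
    rlang::set_names(c("from", "to", "n")) |>
    mutate(n = as.integer(.data$n))
}

#' @rdname tidy.bias_shift
#' @return For `glance()`: a one-row tibble with `n_shared`, `n_stable`
#'   (diagonal count) and `fraction_shifted`.
#' @export
glance.bias_shift <- function(x, ...) {
  stable <- sum(diag(x$transitions))
  tibble(
    n_shared = x$n_shared,
    n_stable = stable,
    fraction_shifted = if (x$n_shared > 0) 1 - stable / x$n_shared else NA_real_
  )
}
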