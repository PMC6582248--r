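# Collinearity-based rearrangement annotation. Homoeologous chromosomes of
# the three wheat subgenomes are largely collinear, so within a triad the
# members' chromosome number and arm should agree. A member that disagrees
# with the majority of its partners is a candidate for one of the known
# rearrangements (4A arm inversion, 4AL/5AL reciprocal translocation,
# 7BS->4AL, ...), matched declaratively against a rule table rather than by
# de novo synteny computation.

chrom_number <- function(chromosome) split_chromosome(chromosome)$number

#' Collinear expectation for one triad
#'
#' Determines, by majority vote over the members' (chromosome number, arm)
#' placements, where each member of a triad is expected to sit. With no
#' majority (e.g. two members that disagree) the triad is indeterminate and
#' every member's expectation is `NA`.
#'
#' @param members A tibble of one triad's roster rows (a `members` element of
#'   [assemble_triads()] output), with at least 2 rows.
#' @return A tibble with one row per member: `subgenome`,
#'   `observed_chromosome`, `observed_arm`, `expected_chromosome` (majority
#'   chromosome number combined with the member's own subgenome letter),
#'   `expected_arm`, and logical `deviant`.
#' @examples
#' roster <- read_roster(triadlens_fixture("table3_roster.tsv"),
#'                       on_mismatch = "flag")
#' tri <- dplyr::filter(roster, gene_name == "tri01")
#' collinear_expectation(tri)
#' @export
collinear_expectation <- function(members) {
  members <- as_tibble(members)
  if (nrow(members) < 2L) {
    abort("Collinear expectation needs at least 2 triad members.",
          class = "triadlens_insufficient_evidence_error")
  }
  num <- chrom_number(members$chromosome)
  arm <- members$arm

  # Majority over joint (number, arm) among known-arm members; fall back to a
  # chromosome-number-only vote (expectation arm unknown) when arms are
  # uninformative.
  key <- ifelse(is.na(arm), NA_character_, paste0(num, arm))
  exp_num <- NA_integer_
  exp_arm <- NA_character_
  tab <- table(key[!is.na(key)])
  if (length(tab) > 0L && max(tab) >= 2L && sum(tab == max(tab)) == 1L) {
    win <- names(tab)[which.max(tab)]
    exp_num <- as.integer(substr(win, 1L, nchar(win) - 1L))
    exp_arm <- substr(win, nchar(win), nchar(win))
  } else {
    ntab <- table(num)
    if (max(ntab) >= 2L && sum(ntab == max(ntab)) == 1L) {
      exp_num <- as.integer(names(ntab)[which.max(ntab)])
    }
  }

  indeterminate <- is.na(exp_num)
  deviant <- if (indeterminate) {
    rep(NA, nrow(members))
  } else if (is.na(exp_arm)) {
    num != exp_num
  } else {
    num != exp_num | (!is.na(arm) & arm != exp_arm)
  }
  tibble(
    subgenome = members$subgenome,
    observed_chromosome = members$chromosome,
    observed_arm = arm,
    expected_chromosome = if (indeterminate) NA_character_ else paste0(exp_num, members$subgenome),
    expected_arm = exp_arm,
    deviant = deviant
  )
}

#' Annotate triads with known chromosome rearrangement events
#'
#' For every triad with at least two members, computes the collinear
#' expectation and matches each deviant member against the rule table by its
#' (observed, expected) chromosome/arm pair. Deviants matching no rule are
#' reported with `event_class = "unexplained_deviation"` rather than dropped;
#' a deviant matching more than one rule is an error (rule tables are meant
#' to be keyed one-to-one). Fully collinear triads emit nothing.
#'
#' @param roster A validated roster tibble, or a triad tibble from
#'   [assemble_triads()].
#' @param rules A rule tibble; defaults to [default_rearrangement_rules()].
#' @return A tibble of assignments: `gene_name`, `rule_id`, `event_label`,
#'   `event_class`, `deviant_subgenome`, `observed_chromosome`,
#'   `observed_arm`, `expected_chromosome`, `expected_arm`,
#'   `homoeologs_involved` (the triad's member count). Gene names of triads
#'   whose expectation was indeterminate are attached as the
#'   `indeterminate_genes` attribute.
#' @examples
#' read_roster(triadlens_fixture("table3_roster.tsv"), on_mismatch = "flag") |>
#'   annotate_rearrangements() |>
#'   event_summary()
#' @export
annotate_rearrangements <- function(roster, rules = default_rearrangement_rules()) {
  rules <- validate_rules(rules)
  triads <- if ("members" %in% names(roster)) as_tibble(roster) else assemble_triads(roster)

  indeterminate <- character()
  out <- purrr::pmap(
    list(triads$gene_name, triads$members, triads$n_members),
    function(gene, members, n_members) {
      if (n_members < 2L) {
        return(NULL)
      }
      exp <- collinear_expectation(members)
      if (all(is.na(exp$deviant))) {
        indeterminate <<- c(indeterminate, gene)
        return(NULL)
      }
      dev <- exp[which(exp$deviant), , drop = FALSE]
      if (nrow(dev) == 0L) {
        return(NULL)
      }
      purrr::pmap(dev, function(subgenome, observed_chromosome, observed_arm,
                                expected_chromosome, expected_arm, deviant) {
        hit <- rules$observed_chrom == observed_chromosome &
          rules$expected_chrom == expected_chromosome &
          (is.na(rules$observed_arm) |
             (!is.na(observed_arm) & rules$observed_arm == observed_arm)) &
          (is.na(rules$expected_arm) |
             (!is.na(expected_arm) & rules$expected_arm == expected_arm))
        hits <- which(hit)
        if (length(hits) > 1L) {
          abort(
            paste0("Deviant ", gene, "/", subgenome, " matches multiple rules: ",
                   paste(rules$rule_id[hits], collapse = ", ")),
            class = "triadlens_ambiguity_error"
          )
        }
        tibble(
          gene_name = gene,
          rule_id = if (length(hits)) rules$rule_id[hits] else NA_character_,
          event_label = if (length(hits)) rules$event_label[hits] else NA_character_,
          event_class = if (length(hits)) rules$event_class[hits] else "unexplained_deviation",
          deviant_subgenome = subgenome,
          observed_chromosome = observed_chromosome,
          observed_arm = observed_arm,
          expected_chromosome = expected_chromosome,
          expected_arm = expected_arm,
          homoeologs_involved = as.integer(n_members)
        )
      }) |> bind_rows()
    }
  )
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble(
      gene_name = character(), rule_id = character(), event_label = character(),
      event_class = character(), deviant_subgenome = character(),
      observed_chromosome = character(), observed_arm = character(),
      expected_chromosome = character(), expected_arm = character(),
      homoeologs_involved = integer()
    )
  }
  res <- arrange(res, .data$gene_name)
  attr(res, "indeterminate_genes") <- sort(indeterminate)
  res
}

#' Summarise rearrangement assignments by event class
#'
#' @param assignments Output of [annotate_rearrangements()].
#' @return A tibble with one row per `event_class`: `n_triads` (distinct
#'   genes) and `n_homoeologs` (total members of those triads).
#' @export
event_summary <- function(assignments) {
  assignments |>
    distinct(.data$event_class, .data$gene_name, .data$homoeologs_involved) |>
    group_by(.data$event_class) |>
    summarise(
      n_triads = dplyr::n_distinct(.data$gene_name),
      n_homoeologs = sum(.data$homoeologs_involved),
      .groups = "drop"
    ) |>
    arrange(.data$event_class)
}
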