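# Packaged desk-scale fixtures: a 257-homoeolog roster realising the family's
# published subgenome-distribution pattern, the 36 homoeolog placements
# involved in known 4A/5A/7B rearrangements, and the default rule table those
# placements are interpreted against.

#' Path to a packaged fixture file
#'
#' @param name File name under the package's `extdata/` directory; with no
#'   argument, lists the available fixtures.
#' @return A file path (or a character vector of file names).
#' @export
triadlens_fixture <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "triadlens")))
  }
  path <- system.file("extdata", name, package = "triadlens")
  if (!nzchar(path)) {
    abort(paste0("No packaged fixture named ", name),
          class = "triadlens_format_error")
  }
  path
}

#' Roster fixture realising the family-wide subgenome distribution
#'
#' Builds a 257-row roster of 95 genes whose triad composition follows the
#' published distribution for the wheat PP2C family: 76 genes with all three
#' homoeologs, 4 AB + 3 AD + 3 BD two-member genes, and 3 + 3 + 3 singletons
#' on A, B and D. Chromosome assignments and coordinates are synthetic (only
#' the pattern structure is meaningful); output is deterministic given `seed`.
#'
#' @param seed Integer seed for the synthetic coordinates.
#' @return A validated roster tibble (257 rows).
#' @export
table1_roster <- function(seed = 101L) {
  patterns <- c(
    rep("ABD", 76L), rep("AB", 4L), rep("AD", 3L), rep("BD", 3L),
    rep("A", 3L), rep("B", 3L), rep("D", 3L)
  )
  genes <- sprintf("g%03d", seq_along(patterns))
  with_seed(seed, {
    rows <- purrr::map2(genes, patterns, function(g, pat) {
      subg <- strsplit(pat, "")[[1]]
      chrom_num <- 1L + (sum(utf8ToInt(g)) %% 7L)
      arm <- if (chrom_num %% 2L == 0L) "L" else "S"
      start <- sample.int(5e8, 1L)
      tibble(
        homoeolog_id = paste0(g, "-", subg),
        gene_name = g,
        subgenome = subg,
        chromosome = paste0(chrom_num, subg),
        arm = arm,
        start_bp = start,
        end_bp = start + sample.int(9000L, 1L) + 500L,
        group_label = LETTERS[1L + (sum(utf8ToInt(g)) %% 13L)]
      )
    })
    validate_roster(bind_rows(rows))
  })
}

#' Roster fixture of homoeologs involved in known wheat rearrangements
#'
#' Encodes the 36 published homoeolog placements (12 triads) affected by the
#' 4A pericentromeric inversion, the 4AL/5AL reciprocal translocation, the
#' 7BS->4AL translocation and the putative 6B arm inversion, using the
#' printed chromosome arms verbatim. The member of the 7BS->4AL triad that
#' physically resides on 4AL keeps its B-lineage subgenome assignment, so the
#' fixture must be read with `on_mismatch = "flag"`. Coordinates are
#' synthetic placeholders.
#'
#' @return A roster tibble (36 rows), validated with `on_mismatch = "flag"`.
#' @export
table3_roster <- function() {
  # gene, homoeolog_id, subgenome(lineage), chromosome+arm
  spec <- list(
    # 4A pericentromeric inversions (5 triads 4AL->4AS, 1 triad 4AS->4AL)
    list("tri01", c("TaPP2C119", "A", "4A", "S"), c("TaPP2C137", "B", "4B", "L"), c("TaPP2C149", "D", "4D", "L")),
    list("tri02", c("TaPP2C121", "A", "4A", "S"), c("TaPP2C135", "B", "4B", "L"), c("TaPP2C147", "D", "4D", "L")),
    list("tri03", c("TaPP2C122", "A", "4A", "S"), c("TaPP2C134", "B", "4B", "L"), c("TaPP2C146", "D", "4D", "L")),
    list("tri04", c("TaPP2C123", "A", "4A", "S"), c("TaPP2C133", "B", "4B", "L"), c("TaPP2C145", "D", "4D", "L")),
    list("tri05", c("TaPP2C124", "A", "4A", "S"), c("TaPP2C132", "B", "4B", "L"), c("TaPP2C144", "D", "4D", "L")),
    list("tri06", c("TaPP2C126", "A", "4A", "L"), c("TaPP2C130", "B", "4B", "S"), c("TaPP2C141", "D", "4D", "S")),
    # 4AL/5AL reciprocal translocations
    list("tri07", c("TaPP2C163", "A", "5A", "L"), c("TaPP2C138", "B", "4B", "L"), c("TaPP2C150", "D", "4D", "L")),
    list("tri08", c("TaPP2C164", "A", "5A", "L"), c("TaPP2C139", "B", "4B", "L"), c("TaPP2C151", "D", "4D", "L")),
    list("tri09", c("TaPP2C127", "A", "4A", "L"), c("TaPP2C176", "B", "5B", "L"), c("TaPP2C187", "D", "5D", "L")),
    # 7BS->4AL translocation: the B-lineage copy resides on 4AL
    list("tri10", c("TaPP2C224", "A", "7A", "S"), c("TaPP2C129", "B", "4A", "L"), c("TaPP2C246", "D", "7D", "S")),
    # putative 6B arm inversion
    list("tri11", c("TaPP2C194", "A", "6A", "S"), c("TaPP2C207", "B", "6B", "L"), c("TaPP2C217", "D", "6D", "S")),
    list("tri12", c("TaPP2C195", "A", "6A", "L"), c("TaPP2C205", "B", "6B", "S"), c("TaPP2C218", "D", "6D", "L"))
  )
  rows <- purrr::imap(spec, function(tri, i) {
    members <- tri[-1]
    purrr::imap(members, function(m, j) {
      start <- 1e6 * i + 1e4 * j
      tibble(
        homoeolog_id = m[[1]], gene_name = tri[[1]], subgenome = m[[2]],
        chromosome = m[[3]], arm = m[[4]],
        start_bp = start, end_bp = start + 3000,
        group_label = "."
      )
    }) |> bind_rows()
  })
  validate_roster(bind_rows(rows), on_mismatch = "flag")
}

#' Default rearrangement rule table
#'
#' Declarative descriptions of the chromosome rearrangements known from the
#' wheat literature that displace genes from collinear expectation: the 4A
#' pericentromeric inversion (arm swap on 4A), the 4AL/5AL reciprocal
#' translocation, the 7BS->4AL and 5AL->7BS legs of the ancient cyclic
#' translocation, 5BS->4BL, and the putative 6B arm inversion (reported under
#' its own class because the event is suggested by synteny, not established).
#'
#' Each rule is keyed one-to-one by the (observed, expected) chromosome/arm
#' pair of the displaced copy: `expected` is where collinearity with the
#' triad partners says the copy should sit, `observed` where it actually is.
#'
#' @return A tibble with columns `rule_id`, `event_label`, `event_class`,
#'   `observed_chrom`, `observed_arm`, `expected_chrom`, `expected_arm`.
#' @export
default_rearrangement_rules <- function() {
  tibble::tribble(
    ~rule_id, ~event_label, ~event_class, ~observed_chrom, ~observed_arm, ~expected_chrom, ~expected_arm,
    "R1", "4AL->4AS", "pericentromeric_inversion", "4A", "S", "4A", "L",
    "R2", "4AS->4AL", "pericentromeric_inversion", "4A", "L", "4A", "S",
    "R3", "4AL->5AL", "reciprocal_translocation", "5A", "L", "4A", "L",
    "R4", "5AL->4AL", "reciprocal_translocation", "4A", "L", "5A", "L",
    "R5", "7BS->4AL", "translocation", "4A", "L", "7B", "S",
    "R6", "5AL->7BS", "translocation", "7B", "S", "5A", "L",
    "R7", "5BS->4BL", "translocation", "4B", "L", "5B", "S",
    "R8", "6BS->6BL", "putative_pericentromeric_inversion", "6B", "L", "6B", "S",
    "R9", "6BL->6BS", "putative_pericentromeric_inversion", "6B", "S", "6B", "L"
  )
}

#' Read a rearrangement rule table from TSV
#'
#' @param path TSV with the columns of [default_rearrangement_rules()].
#' @return A validated rule tibble.
#' @export
read_rearrangement_rules <- function(path) {
  assert_file_exists(path)
  rules <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  validate_rules(rules)
}

validate_rules <- function(rules) {
  rules <- as_tibble(rules)
  required <- c(
    "rule_id", "event_label", "event_class",
    "observed_chrom", "observed_arm", "expected_chrom", "expected_arm"
  )
  missing_cols <- setdiff(required, names(rules))
  if (length(missing_cols) > 0L) {
    abort(
      paste0("Rule table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "triadlens_format_error"
    )
  }
  split_chromosome(rules$observed_chrom)
  split_chromosome(rules$expected_chrom)
  for (col in c("observed_arm", "expected_arm")) {
    rules[[col]][rules[[col]] %in% c(".", "")] <- NA_character_
  }
  arm_eq <- (is.na(rules$observed_arm) & is.na(rules$expected_arm)) |
    (!is.na(rules$observed_arm) & !is.na(rules$expected_arm) &
       rules$observed_arm == rules$expected_arm)
  same <- rules$observed_chrom == rules$expected_chrom & arm_eq
  if (any(same)) {
    abort(
      paste0("Rule(s) with observed == expected: ",
             paste(rules$rule_id[same], collapse = ", ")),
      class = "triadlens_validation_error"
    )
  }
  key <- paste(rules$observed_chrom, rules$observed_arm,
               rules$expected_chrom, rules$expected_arm)
  if (anyDuplicated(key)) {
    abort("Rule table has duplicate (observed, expected) keys.",
          class = "triadlens_validation_error")
  }
  rules[required]
}

#' Write the packaged fixtures to disk
#'
#' Writes `table1_roster.tsv`, `table3_roster.tsv` and
#' `rearrangement_rules.tsv` to `dir`, in the dialects the readers consume.
#' Output is byte-identical for a given `seed`.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed forwarded to [table1_roster()].
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir, seed = 101L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c(
    "table1_roster.tsv", "table3_roster.tsv", "rearrangement_rules.tsv"
  ))
  write_fix <- function(x, path) {
    for (col in intersect(c("start_bp", "end_bp"), names(x))) {
      x[[col]] <- format(x[[col]], scientific = FALSE, trim = TRUE)
    }
    readr::write_tsv(x, path, na = ".", progress = FALSE)
  }
  write_fix(select(table1_roster(seed), -"translocated"), paths[1])
  write_fix(select(table3_roster(), -"translocated"), paths[2])
  write_fix(default_rearrangement_rules(), paths[3])
  invisible(paths)
}
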