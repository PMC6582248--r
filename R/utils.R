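# Shared internal helpers.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# A NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# chromosome string "4A" -> list(number = 4L, letter = "A")
split_chromosome <- function(chromosome) {
  ok <- grepl("^[1-7][ABD]$", chromosome)
  if (!all(ok)) {
    abort(
      paste0(
        "Invalid chromosome name(s): ",
        paste(unique(chromosome[!ok]), collapse = ", "),
        " (expected e.g. \"4A\", i.e. [1-7][ABD])."
      ),
      class = "triadlens_validation_error"
    )
  }
  list(
    number = as.integer(substr(chromosome, 1L, 1L)),
    letter = substr(chromosome, 2L, 2L)
  )
}

assert_file_exists <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(
      paste0("File not found: ", path),
      class = "triadlens_format_error"
    )
  }
  invisible(path)
}

# Subgenome pattern string ("ABD", "AD", "B", ...) from a character vector of
# subgenomes present in a triad.
subgenome_pattern <- function(subgenomes) {
  paste(SUBGENOMES[SUBGENOMES %in% subgenomes], collapse = "")
}
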