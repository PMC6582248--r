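# Independent brute-force oracles for the NG86 counting rules, implemented
# differently from the package (explicit mutant enumeration; recursive
# depth-first pathway walk instead of precomputed permutation lists).

oracle_code <- function() {
  setNames(as.character(Biostrings::GENETIC_CODE),
           names(Biostrings::GENETIC_CODE))
}

# Fractional synonymous sites: enumerate all 9 single-nucleotide mutants.
oracle_codon_sites <- function(codon, code = oracle_code()) {
  nts <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  syn <- 0
  for (pos in 1:3) {
    for (nt in nts) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (code[[mut]] != "*" && code[[mut]] == aa) syn <- syn + 1
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

# Pathway-averaged differences: recursive DFS over orders of the remaining
# differing positions; paths through stop codons are dropped (all paths kept,
# stop steps counted nonsynonymous, if every path is blocked).
oracle_codon_diff <- function(c1, c2, code = oracle_code()) {
  paths <- list()
  walk <- function(cur, sd, nd, blocked) {
    remaining <- which(strsplit(cur, "")[[1]] != strsplit(c2, "")[[1]])
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd, blocked = blocked)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      step_stop <- code[[nxt]] == "*" || code[[cur]] == "*"
      syn <- !step_stop && code[[nxt]] == code[[cur]]
      walk(nxt, sd + syn, nd + !syn, blocked || step_stop)
    }
  }
  walk(c1, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  open <- m[, "blocked"] == 0
  if (!any(open)) open <- rep(TRUE, nrow(m))
  c(sd = mean(m[open, "sd"]), nd = mean(m[open, "nd"]))
}

# Random points on the 2-simplex (uniform Dirichlet(1,1,1)).
random_simplex <- function(n) {
  g <- matrix(stats::rexp(3 * n), ncol = 3)
  g / rowSums(g)
}

# A minimal well-formed roster TSV written to a temp file.
write_roster_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- paste(
    "homoeolog_id", "gene_name", "subgenome", "chromosome", "arm",
    "start_bp", "end_bp", "group_label", sep = "\t"
  )
  writeLines(c(header, rows), path)
  path
}
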