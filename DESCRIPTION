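Package: triadlens
Title: Homoeolog Triad Bookkeeping, Expression Bias and Ka/Ks for Allopolyploid Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for homoeolog-centric analysis of gene families in
    allohexaploid wheat and similar polyploids. Assembles A/B/D homoeolog
    triads from a gene roster and summarises their subgenome distribution;
    annotates triads whose members deviate from collinear expectation and
    matches them to known chromosome translocation and pericentromeric
    inversion events via a declarative rule table; classifies per-triad
    relative expression abundances (from TPM) into seven homoeolog-bias
    categories with ternary-plot coordinates and cross-condition shift
    tables; and estimates Ka/Ks for pairs of aligned in-frame coding
    sequences with the Nei-Gojobori (1986) counting method and Jukes-Cantor
    correction. A synthetic-data module generates rosters, biased triad
    expression matrices, condition-shift pairs and codon alignments evolved
    under a known omega, so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
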