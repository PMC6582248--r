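test_that("fractional site counts match mutant enumeration", {
  cs <- codon_sites(c("GGG", "ATG", "AAA"))
  expect_equal(cs$s, c(1, 0, 1 / 3))
  expect_equal(cs$n, c(2, 3, 8 / 3))

  # every sense codon agrees with the independent 9-mutant oracle
  code <- standard_genetic_code()
  sense <- names(code)[code != "*"]
  all_sites <- codon_sites(sense)
  oracle <- t(vapply(sense, oracle_codon_sites, numeric(2)))
  expect_equal(all_sites$s, unname(oracle[, "s"]))
  expect_true(all(abs(all_sites$s + all_sites$n - 3) < 1e-12))

  expect_error(codon_sites("TAA"), class = "triadlens_validation_error")
  expect_error(codon_sites("NNN"), class = "triadlens_validation_error")
})

test_that("pathway-averaged differences handle multi-hit codons and blocked paths", {
  d <- codon_differences(
    c("TTT", "GGG", "TTT"), c("TTT", "GGA", "GTA")
  )
  expect_equal(d$sd, c(0, 1, 0.5))
  expect_equal(d$nd, c(0, 0, 1.5))

  # sd + nd equals the number of differing positions when no path is blocked
  withr::with_seed(17, {
    code <- standard_genetic_code()
    sense <- names(code)[code != "*"]
    c1 <- sample(sense, 50, replace = TRUE)
    c2 <- sample(sense, 50, replace = TRUE)
    k <- mapply(\(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), c1, c2)
    dd <- codon_differences(c1, c2)
    oracle <- mapply(\(a, b) oracle_codon_diff(a, b), c1, c2)
    expect_equal(dd$sd, unname(oracle["sd", ]))
    expect_equal(dd$nd, unname(oracle["nd", ]))
    expect_true(all(abs(dd$sd + dd$nd - k) < 1e-12))
  })

  # with every pathway blocked (engineered code), all paths are used with a
  # warning and steps through the stop count as nonsynonymous
  code2 <- standard_genetic_code()
  code2[c("ACA", "AAC")] <- "*"
  expect_warning(
    d2 <- codon_differences("AAA", "ACC", code = code2),
    "stop"
  )
  expect_equal(d2$sd + d2$nd, 2)

  expect_error(codon_differences("TAA", "AAA"),
               class = "triadlens_validation_error")
})

test_that("Jukes-Cantor correction has the closed form and saturates at 3/4", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.5), -0.75 * log(1 / 3))
  expect_true(is.na(jukes_cantor(0.75)))
  expect_error(jukes_cantor(-0.1), class = "triadlens_validation_error")
  expect_error(jukes_cantor(1.1), class = "triadlens_validation_error")
  p <- seq(0, 0.74, by = 0.02)
  expect_true(all(diff(jukes_cantor(p)) > 0))
})

test_that("ng86 reproduces hand-enumerated pairs and flags saturation", {
  # identical sequences: both rates zero, ratio undefined via Ks = 0
  pair <- simulate_codon_pair(n_codons = 300, expected_subs_per_codon = 0,
                              seed = 2)
  res <- ng86(pair$seq1, pair$seq2)
  expect_equal(c(res$Ka, res$Ks, res$Sd, res$Nd), c(0, 0, 0, 0))
  expect_true(is.na(res$ratio))
  expect_false(res$flags[["saturated_s"]])
  expect_false(res$flags[["saturated_n"]])
  expect_true(res$flags[["zero_ks"]])

  # two-codon pair with one synonymous difference, hand-enumerated
  res2 <- ng86("GGGAAA", "GGAAAA")
  expect_equal(res2$S, 4 / 3)
  expect_equal(res2$N, 14 / 3)
  expect_equal(c(res2$Sd, res2$Nd), c(1, 0))
  expect_equal(res2$pS, 0.75)
  expect_true(res2$flags[["saturated_s"]])
  expect_true(is.na(res2$Ks))
  expect_true(is.na(res2$ratio))

  # Ka = 0 with Ks > 0 reports a ratio of exactly zero
  res3 <- ng86("GGGAAAGGGAAA", "GGCAAAGGGAAA")
  expect_equal(res3$Nd, 0)
  expect_gt(res3$Ks, 0)
  expect_equal(res3$ratio, 0)

  expect_error(ng86("AAAT", "AAAA"), class = "triadlens_validation_error")
  expect_error(ng86("AAA", "AAAAAA"), class = "triadlens_validation_error")
  expect_error(ng86("TAAAAA", "TACAAA"), class = "triadlens_validation_error")
})

test_that("ng86 is symmetric, additive over concatenation, and skips gap codons pairwise", {
  pair <- simulate_codon_pair(n_codons = 200, omega = 0.5,
                              expected_subs_per_codon = 0.3, seed = 7)
  a <- ng86(pair$seq1, pair$seq2)
  b <- ng86(pair$seq2, pair$seq1)
  expect_equal(tidy(a), tidy(b))
  expect_equal(a$S + a$N, 3 * a$n_codons)

  # concatenation: counts add over the parts
  pair2 <- simulate_codon_pair(n_codons = 150, omega = 0.5,
                               expected_subs_per_codon = 0.3, seed = 8)
  whole <- ng86(paste0(pair$seq1, pair2$seq1), paste0(pair$seq2, pair2$seq2))
  part <- ng86(pair2$seq1, pair2$seq2)
  for (f in c("S", "N", "Sd", "Nd")) {
    expect_equal(whole[[f]], a[[f]] + part[[f]])
  }

  # a gap codon in either sequence removes that codon pair from both
  gapped1 <- paste0("---", substr(pair$seq1, 4, nchar(pair$seq1)))
  res <- ng86(gapped1, pair$seq2)
  expect_equal(res$n_codons, 199L)
  expect_equal(res$n_skipped, 1L)
  expect_equal(res$S + res$N, 3 * 199)
})

test_that("pair tables join manifests to sequences and summarise by group", {
  seqs <- c(x1 = "GGGAAA", x2 = "GGGAAA", y1 = "GGGAAA", y2 = "GGGAAA")
  pairs <- tibble::tibble(pair_id = c("p1", "p2"), id1 = c("x1", "y1"),
                          id2 = c("x2", "y2"))
  tab <- pair_kaks_table(pairs, seqs)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$Ka, c(0, 0))
  expect_equal(tab$Ks, c(0, 0))

  expect_equal(nrow(pair_kaks_table(pairs[0, ], seqs)), 0L)
  expect_error(
    pair_kaks_table(tibble::tibble(pair_id = "p", id1 = "x1", id2 = "nope"), seqs),
    class = "triadlens_manifest_error"
  )

  # simulated groups under weak vs strong purifying selection order correctly
  batch <- simulate_codon_pairs(n_pairs = 5, omega = c(0.1, 0.5),
                                n_codons = 400, seed = 71)
  tab2 <- pair_kaks_table(batch$pairs, batch$sequences)
  gm <- group_mean_kaks(tab2)
  expect_equal(gm$n_used, c(5L, 5L))
  expect_lt(gm$mean_ratio[gm$group == "omega_0.1"],
            gm$mean_ratio[gm$group == "omega_0.5"])

  # FASTA round trip through the same interface
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(batch$sequences), "\n", batch$sequences), fa)
  tab3 <- pair_kaks_table(batch$pairs, fa)
  expect_equal(tab3$ratio, tab2$ratio)
})
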