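test_that("relative abundance normalises TPM triplets and applies the expression filter", {
  r <- relative_abundance(c(10, 2, 0), c(10, 1, 0), c(10, 1, 0),
                          min_total_tpm = 0.5)
  expect_equal(r$r_A, c(1 / 3, 0.5, NA))
  expect_equal(r$r_B, c(1 / 3, 0.25, NA))
  expect_equal(r$r_D, c(1 / 3, 0.25, NA))
  expect_equal(r$expressed, c(TRUE, TRUE, FALSE))
  expect_error(relative_abundance(-1, 1, 1),
               class = "triadlens_validation_error")

  # expressed rows always sum to exactly 1 (within 1e-9)
  withr::with_seed(5, {
    tpm <- matrix(stats::runif(300, 0, 50), ncol = 3)
    rr <- relative_abundance(tpm[, 1], tpm[, 2], tpm[, 3])
    expect_true(all(abs(rr$r_A + rr$r_B + rr$r_D - 1)[rr$expressed] < 1e-9))
  })
})

test_that("each centroid classifies to itself and near-boundary points go to the nearest centroid", {
  cen <- bias_centroids()
  expect_equal(nrow(cen), 7L)
  got <- classify_bias(cen$r_A, cen$r_B, cen$r_D)
  expect_equal(as.character(got), cen$category)
  expect_equal(levels(got), cen$category)

  # nearest-centroid call for a strongly A-suppressed point, checked against
  # an explicit distance computation
  p <- c(0.05, 0.475, 0.475)
  d <- apply(bias_centroids(as_matrix = TRUE), 1, \(c) sqrt(sum((p - c)^2)))
  expect_equal(names(which.min(d)), "A_suppressed")
  expect_equal(as.character(classify_bias(p[1], p[2], p[3])), "A_suppressed")

  # exact ties resolve to Balanced (midpoint of Balanced and D_suppressed)
  expect_equal(as.character(classify_bias(5 / 12, 5 / 12, 1 / 6)), "Balanced")

  # off-simplex input is rejected
  expect_error(classify_bias(0.6, 0.6, 0.6),
               class = "triadlens_validation_error")

  # optional forced-Balanced ball
  expect_equal(
    as.character(classify_bias(0.30, 0.30, 0.40, balanced_radius = 0.2)),
    "Balanced"
  )
})

test_that("classification is equivariant under subgenome permutation and scale-free", {
  perms <- list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1), c(1, 3, 2), c(2, 3, 1), c(3, 1, 2))
  relab <- function(cat, perm) {
    if (cat == "Balanced") return("Balanced")
    parts <- strsplit(cat, "_")[[1]]
    to <- c("A", "B", "D")[match(match(parts[1], c("A", "B", "D")), perm)]
    paste0(to, "_", parts[2])
  }
  pts <- withr::with_seed(9, random_simplex(40))
  base <- as.character(classify_bias(pts[, 1], pts[, 2], pts[, 3]))
  for (perm in perms) {
    permuted <- pts[, perm, drop = FALSE]
    got <- as.character(classify_bias(permuted[, 1], permuted[, 2], permuted[, 3]))
    expect_equal(got, vapply(base, relab, character(1), perm = perm,
                             USE.NAMES = FALSE))
  }
  # scale-free: category depends on rel only, not on the TPM totals behind it
  scaled <- relative_abundance(pts[, 1] * 1000, pts[, 2] * 1000, pts[, 3] * 1000)
  expect_equal(as.character(classify_bias(scaled$r_A, scaled$r_B, scaled$r_D)),
               base)
})

test_that("ternary coordinates hit the corners and invert exactly", {
  xy <- ternary_coordinates(c(1, 0, 0, 1 / 3), c(0, 1, 0, 1 / 3),
                            c(0, 0, 1, 1 / 3))
  expect_equal(xy$x, c(0, 1, 0.5, 0.5))
  expect_equal(xy$y, c(0, 0, sqrt(3) / 2, sqrt(3) / 6))
  expect_error(ternary_coordinates(0.9, 0.9, 0.9),
               class = "triadlens_validation_error")

  pts <- withr::with_seed(13, random_simplex(200))
  fwd <- ternary_coordinates(pts[, 1], pts[, 2], pts[, 3])
  back <- ternary_to_simplex(fwd$x, fwd$y)
  expect_true(max(abs(as.matrix(back) - pts)) < 1e-12)
})

test_that("log transform is log2(TPM + 1), keeping missing cells missing", {
  expect_equal(log_transform_tpm(c(0, 1, 7)), c(0, 1, 3))
  expr <- tibble::tibble(homoeolog_id = c("a", "b"), s1 = c(7, NA), s2 = c(0, 3))
  lt <- log_transform_tpm(expr)
  expect_equal(lt$s1, c(3, NA))
  expect_equal(lt$s2, c(0, 2))
  expect_error(log_transform_tpm(c(-1, 2)), class = "triadlens_validation_error")
})

test_that("triads incomplete in expression are excluded from selection", {
  sim <- simulate_triad_expression(n_triads = 5, seed = 21)
  full <- select_complete_triads(sim$expr, sim$roster)
  expect_equal(nrow(full), 5L)

  # drop one D row: that triad goes
  expr <- sim$expr[sim$expr$homoeolog_id != "sim0003-D", ]
  kept <- select_complete_triads(expr, sim$roster)
  expect_equal(nrow(kept), 4L)
  expect_false("sim0003" %in% kept$gene_name)

  # a missing (NA) cell in a chosen condition also excludes the triad,
  # whereas an observed zero keeps it
  expr2 <- sim$expr
  expr2$control[expr2$homoeolog_id == "sim0001-A"] <- NA
  expr2$control[expr2$homoeolog_id == "sim0002-A"] <- 0
  kept2 <- select_complete_triads(expr2, sim$roster)
  expect_setequal(kept2$gene_name, c("sim0002", "sim0003", "sim0004", "sim0005"))
})

test_that("a 53-of-76 complete fixture retains 159 homoeologs", {
  sim <- simulate_triad_expression(n_triads = 76, seed = 33)
  drop_genes <- sprintf("sim%04d", 1:23)
  expr <- sim$expr[!sim$expr$homoeolog_id %in% paste0(drop_genes, "-D"), ]
  kept <- select_complete_triads(expr, sim$roster)
  expect_equal(nrow(kept), 53L)
  expect_equal(sum(kept$n_members), 159L)
})

test_that("the bias pipeline aggregates replicates per condition and classifies triads", {
  # three replicates of one condition; mean vs median aggregation
  expr <- tibble::tibble(
    homoeolog_id = c("g1-A", "g1-B", "g1-D"),
    s1 = c(2, 1, 1), s2 = c(3, 1, 1), s3 = c(10, 1, 1)
  )
  roster <- validate_roster(tibble::tibble(
    homoeolog_id = c("g1-A", "g1-B", "g1-D"), gene_name = "g1",
    subgenome = c("A", "B", "D"), chromosome = c("1A", "1B", "1D"),
    arm = "L", start_bp = 1, end_bp = 2, group_label = "."
  ))
  meta <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"), tissue = "leaf", stage = "x",
    condition = "ck", replicate = c("1", "2", "3")
  )
  b_mean <- triad_bias(expr, roster, meta)
  expect_equal(b_mean$tpm_A, 5)  # mean of 2, 3, 10
  expect_equal(b_mean$r_A, 5 / 7)
  expect_equal(as.character(b_mean$category), "A_dominant")
  b_med <- triad_bias(expr, roster, meta, agg = "median")
  expect_equal(b_med$tpm_A, 3)
  expect_equal(as.character(b_med$category), "Balanced")

  # below the expression filter nothing is classified
  low <- triad_bias(
    dplyr::mutate(expr, s1 = s1 / 100, s2 = s2 / 100, s3 = s3 / 100),
    roster, meta
  )
  expect_false(low$expressed)
  expect_true(is.na(low$category))

  expect_error(triad_bias(expr, roster, meta, conditions = "absent"),
               class = "triadlens_configuration_error")
})

test_that("shift tables cross-tabulate category transitions between conditions", {
  sim <- simulate_triad_expression(n_triads = 40, seed = 41)
  b1 <- triad_bias(sim$expr, sim$roster)

  # identical classifications give a purely diagonal matrix
  b1b <- dplyr::mutate(b1, condition = "again")
  st <- shift_table(b1, b1b)
  expect_equal(sum(st$transitions), st$n_shared)
  expect_equal(sum(diag(st$transitions)), st$n_shared)
  expect_equal(glance(st)$fraction_shifted, 0)

  # a single engineered Balanced -> B_dominant move shows up off-diagonal
  moved <- b1
  bal <- which(moved$category == "Balanced")[1]
  moved$category[bal] <- "B_dominant"
  moved$condition <- "stress"
  st2 <- shift_table(b1, moved)
  expect_equal(st2$transitions["Balanced", "B_dominant"], 1L)
  expect_equal(sum(st2$transitions) - sum(diag(st2$transitions)), 1L)

  td <- tidy(st2)
  expect_equal(sum(td$n), st2$n_shared)
  expect_equal(nrow(td), 49L)

  # per-subgenome tallies count dominant/suppressed triads per condition
  ps <- st2$per_subgenome
  expect_setequal(unique(ps$condition), c("control", "stress"))
  expect_equal(
    ps$n_dominant[ps$condition == "stress" & ps$subgenome == "B"],
    sum(moved$category == "B_dominant")
  )

  # duplicated gene within one condition is rejected
  expect_error(shift_table(dplyr::bind_rows(b1, b1[1, ]), b1b),
               class = "triadlens_validation_error")
})

test_that("bias plots build without error", {
  sim <- simulate_triad_expression(n_triads = 15, seed = 51)
  b1 <- triad_bias(sim$expr, sim$roster)
  p1 <- plot_ternary(b1)
  expect_s3_class(p1, "ggplot")
  b2 <- dplyr::mutate(b1, condition = "stress")
  p2 <- autoplot(shift_table(b1, b2))
  expect_s3_class(p2, "ggplot")
})
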