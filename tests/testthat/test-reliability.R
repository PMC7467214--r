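test_that("ICC(A,2) handles the canonical worked cases", {
  # perfect agreement: MSE = MSC = 0 -> icc exactly 1
  r <- compute_icc_ak(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_identical(r$icc, 1)
  expect_identical(r$MSE, 0)
  expect_identical(r$MSC, 0)

  # worked 4x2 example: MSR = 40/3, MSC = 2, MSE = 0 -> (40/3)/(40/3 + 2/4)
  r2 <- compute_icc_ak(cbind(c(1, 3, 5, 7), c(2, 4, 6, 8)))
  expect_equal(r2$MSR, 40 / 3)
  expect_equal(r2$MSC, 2)
  expect_equal(r2$MSE, 0)
  expect_equal(r2$icc, 80 / 83, tolerance = 1e-12)

  # a constant offset is penalized by absolute agreement but not by Pearson
  x <- cbind(c(0.1, 0.4, 0.7), c(0.1, 0.4, 0.7) + 0.2)
  expect_lt(compute_icc_ak(x)$icc, 1)
  expect_equal(compute_pearson(x)$r, 1)
})

test_that("ICC matches the brute-force two-way ANOVA oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    x <- matrix(rnorm(2 * n, sd = runif(1, 0.1, 2)), n, 2) + rnorm(1)
    expect_equal(compute_icc_ak(x)$icc, icc_aov_oracle(x), tolerance = 1e-10)
  }
})

test_that("degenerate and undersized probes are flagged, not fatal", {
  expect_identical(compute_icc_ak(matrix(0.5, 4, 2))$flag, "degenerate")
  expect_identical(compute_icc_ak(matrix(c(1, 2, 1, 2), 2, 2))$flag,
                   "insufficient_n")
  expect_identical(compute_pearson(cbind(rep(1, 5), 1:5))$flag, "zero_variance")
})

test_that("Pearson matches the textbook formula oracle", {
  expect_equal(compute_pearson(cbind(1:3, c(2, 4, 6)))$r, 1)
  expect_equal(compute_pearson(cbind(1:3, c(3, 2, 1)))$r, -1)
  set.seed(7)
  x <- matrix(rnorm(100), 50, 2)
  expect_equal(compute_pearson(x)$r,
               pearson_formula_oracle(x[, 1], x[, 2]), tolerance = 1e-12)
})

test_that("icc never exceeds 1 and responds to offsets as absolute agreement requires", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    subj <- rnorm(n)
    x <- cbind(subj + rnorm(n, sd = 0.5), subj + rnorm(n, sd = 0.5))
    r0 <- compute_icc_ak(x)
    expect_lte(r0$icc, 1)
    # common affine rescaling leaves icc unchanged
    r_aff <- compute_icc_ak(2.5 * x + 1)
    expect_equal(r_aff$icc, r0$icc, tolerance = 1e-10)
    # a large constant added to one column decreases icc, not pearson
    # (the shift must dominate the realized column-mean difference)
    x_off <- x; x_off[, 2] <- x_off[, 2] + 10
    expect_lt(compute_icc_ak(x_off)$icc, r0$icc)
    expect_equal(compute_pearson(x_off)$r, compute_pearson(x)$r)
  }
})

test_that("vectorized per-probe ICC agrees with the per-probe function", {
  set.seed(9)
  A <- matrix(runif(200), 20, 10)
  B <- pmin(pmax(A + rnorm(200, sd = 0.1), 0), 1)
  A[1, 3] <- NA; B[2, 5] <- NA  # exercise complete-pairs handling
  v <- methrel:::icc_vec(A, B)
  for (i in 1:20) {
    one <- compute_icc_ak(cbind(A[i, ], B[i, ]))
    expect_equal(v$icc[i], one$icc, tolerance = 1e-12)
    expect_equal(v$n[i], one$n)
  }
})

test_that("reliability_table summarizes per probe and is shuffle-invariant", {
  A <- make_beta(rbind(c(0.1, 0.4, 0.7, 0.9), c(0.2, 0.3, 0.6, 0.8)))
  B1 <- A$values                       # probe 1: perfect agreement
  B1[2, ] <- pmin(B1[2, ] + 0.1, 1)    # probe 2: offset
  B <- make_beta(B1)
  tbl <- reliability_table(pair_matrices(A, B))
  expect_equal(tbl$icc[1], 1)
  expect_lt(tbl$icc[2], 1)
  expect_equal(tbl$mean_beta, unname(rowMeans(A$values)))
  expect_equal(tbl$n_pairs, c(4L, 4L))

  sim <- simulate_reliability_panel(50, 30, seed = 3)
  t1 <- reliability_table(sim$paired)
  perm <- sample(50)
  shuf <- structure(list(
    first = make_beta(sim$paired$first$values[perm, ],
                      probes = rownames(sim$paired$first$values)[perm]),
    second = make_beta(sim$paired$second$values[perm, ],
                       probes = rownames(sim$paired$second$values)[perm])),
    class = "paired_beta")
  t2 <- reliability_table(shuf)
  expect_equal(t2[order(t2$probe_id), ], t1[order(t1$probe_id), ],
               ignore_attr = TRUE)
})

test_that("NA cells reduce to complete pairs per probe", {
  set.seed(21)
  A <- matrix(runif(60), 3, 20); B <- matrix(runif(60), 3, 20)
  A[1, 1:4] <- NA; B[1, 5] <- NA
  v <- methrel:::icc_vec(A, B)
  keep <- !is.na(A[1, ]) & !is.na(B[1, ])
  manual <- compute_icc_ak(cbind(A[1, keep], B[1, keep]))
  expect_equal(v$icc[1], manual$icc, tolerance = 1e-12)
  expect_equal(v$n[1], 15L)
})

test_that("reliability categories use the conventional cutpoints", {
  expect_identical(classify_reliability(c(-0.28, 0.3, 0.4, 0.5, 0.6, 0.75, 0.76, NA)),
                   c("poor", "poor", "fair", "fair", "good", "good",
                     "excellent", NA))
})

test_that("icc and pearson rank probes nearly identically without rater offsets", {
  cfg <- generator_config(400, 200, rater_offset_sd = 0)
  iccs <- seq(0.05, 0.95, length.out = 400)
  sim <- generate_paired(cfg, iccs, seed = 17)
  tbl <- reliability_table(sim$paired)
  expect_gt(cor(tbl$icc, tbl$pearson_r, method = "spearman"), 0.995)
})

test_that("M-value transform is symmetric, exact in the interior, finite at bounds", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b))
  expect_true(all(is.finite(beta_to_m(c(0, 1)))))
  expect_error(beta_to_m(1.1), "\\[0,1\\]")
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(signif(bonferroni_threshold(0.05, 438593), 3), 1.14e-7)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 28000), 3), 1.79e-6)
})
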