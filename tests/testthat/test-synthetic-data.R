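test_that("default true-ICC mixture meets its calibration windows", {
  cfg <- generator_config(50000, 10)
  x <- draw_true_iccs(cfg, seed = 1)
  expect_gte(median(x), 0.05); expect_lte(median(x), 0.13)
  expect_gte(mean(x), 0.17);   expect_lte(mean(x), 0.25)
  expect_gte(mean(x > 0.75), 0.04); expect_lte(mean(x > 0.75), 0.09)
})

test_that("degenerate mixtures behave as constructed", {
  mix_point <- list(weights = c(point = 1, low = 0, mid = 0, high = 0),
                    point_value = 0.9,
                    shapes = default_icc_mixture()$shapes)
  cfg <- generator_config(100, 10, icc_mixture = mix_point)
  expect_true(all(draw_true_iccs(cfg, seed = 2) == 0.9))

  mix_low <- default_icc_mixture()
  mix_low$weights <- c(point = 1, low = 0, mid = 0, high = 0)
  cfg2 <- generator_config(5000, 10, icc_mixture = mix_low)
  expect_lt(median(draw_true_iccs(cfg2, seed = 3)), 0.05)

  bad <- default_icc_mixture(); bad$weights[1] <- 0.5
  expect_error(generator_config(10, 10, icc_mixture = bad), "sum to 1")
  expect_error(generator_config(10, 10, rater_offset_sd = 2), "infeasible")
})

test_that("paired generator recovers target ICCs and rejects icc = 1", {
  cfg <- generator_config(200, 350)
  sim <- generate_paired(cfg, rep(0.97, 200), seed = 4)
  tbl <- reliability_table(sim$paired)
  expect_true(all(tbl$icc > 0.9))
  expect_true(all(sim$paired$first$values > 0 & sim$paired$first$values < 1))
  expect_error(generate_paired(cfg, rep(1, 200), seed = 4), "zero noise")

  # determinism and ground-truth emission
  sim2 <- generate_paired(cfg, rep(0.5, 200), seed = 9)
  sim3 <- generate_paired(cfg, rep(0.5, 200), seed = 9)
  expect_identical(sim2$paired$first$values, sim3$paired$first$values)
  expect_identical(names(sim2$truth),
                   c("probe_id", "true_icc", "mu_logit", "sigma_T", "sigma_E",
                     "offset_1", "offset_2"))
})

test_that("a constant probe surfaces as degenerate downstream", {
  a <- make_beta(matrix(0.3, 2, 10)); b <- make_beta(matrix(0.3, 2, 10))
  tbl <- reliability_table(pair_matrices(a, b))
  expect_true(all(tbl$flag == "degenerate"))
  expect_true(all(is.na(tbl$icc)))
})

test_that("twin generator matches model-implied correlations", {
  tw <- generate_twins(rep(0.6, 200), rep(0.2, 200), rep(0.2, 200),
                       n_mz = 1000, n_dz = 1000, seed = 21)
  r_mz <- vapply(1:200, function(i)
    cor(tw$panel$mz1[i, ], tw$panel$mz2[i, ]), 0)
  r_dz <- vapply(1:200, function(i)
    cor(tw$panel$dz1[i, ], tw$panel$dz2[i, ]), 0)
  expect_equal(mean(r_mz), 0.8, tolerance = 0.03)
  expect_equal(mean(r_dz), 0.5, tolerance = 0.03)
})

test_that("the measurement-error add-on couples low reliability to high E", {
  cfg <- generator_config(500, 10)
  iccs <- draw_true_iccs(cfg, seed = 22)
  iccs <- pmax(iccs, 0.02)
  tw <- generate_twins(rep(0.6, 500), rep(0.2, 500), rep(0.2, 500),
                       n_mz = 200, n_dz = 200,
                       measurement_error = TRUE, true_iccs = iccs, seed = 23)
  expect_lt(cor(iccs, tw$truth$e2_realized), 0)
  expect_gt(cor(iccs, tw$truth$a2_realized), 0)
  expect_equal(tw$truth$a2_realized + tw$truth$c2_realized +
                 tw$truth$e2_realized, rep(1, 500), tolerance = 1e-12)
})

test_that("study-hit generator honors extreme couplings", {
  pid <- sprintf("P%06d", 1:300)
  iccs <- seq(0.01, 0.97, length.out = 300)
  effects <- pid[1:100]
  always <- generate_study_hits(iccs, pid, effects, n_studies = 5,
                                base_detect = 0.99,
                                coupling = function(icc) rep(1, length(icc)),
                                flip_prob = 0, fp_rate = 0, seed = 24)
  counts <- count_replications(always)
  expect_equal(sort(counts$probe_id), sort(effects))
  expect_true(all(counts$n_consistent == 5))

  h1 <- generate_study_hits(iccs, pid, effects, seed = 25)
  h2 <- generate_study_hits(iccs, pid, effects, seed = 25)
  expect_identical(h1, h2)
})

test_that("expression generator is exact at zero noise", {
  sim <- simulate_reliability_panel(50, 30, seed = 26)
  beta <- sim$paired$first
  links <- data.frame(probe_id = rownames(beta$values)[1:10],
                      unit_id = paste0("U", 1:10))
  expr <- generate_expression(beta, links, effect_probes = links$probe_id,
                              effect_size = 1.5, noise_sd = 0, seed = 27)
  expect_equal(expr["U3", ], 1.5 * beta$values[links$probe_id[3], ],
               tolerance = 1e-12)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_reliability_panel(20, 10, seed = 99))
  expect_identical(.Random.seed, before)
})
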