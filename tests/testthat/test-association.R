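rel_from <- function(icc) data.frame(probe_id = sprintf("P%05d", seq_along(icc)),
                                     icc = icc, stringsAsFactors = FALSE)

test_that("external association recovers identity and null couplings", {
  icc <- seq(0.01, 0.97, length.out = 300)
  rel <- rel_from(icc)
  stat <- data.frame(probe_id = rel$probe_id, value = icc)
  expect_equal(associate_external(rel, stat, "pearson")$correlation, 1)
  expect_equal(associate_external(rel, stat, "spearman")$correlation, 1)

  set.seed(19)
  stat$value <- runif(300)  # independent of icc
  out <- associate_external(rel, stat)
  expect_lt(abs(out$correlation), 3 / sqrt(out$n))

  stat$value <- 0.5
  expect_identical(associate_external(rel, stat)$flag, "zero_variance")
})

test_that("monotone coupling strengthens as noise shrinks", {
  set.seed(23)
  icc <- runif(400)
  rel <- rel_from(icc)
  rho <- vapply(c(1, 0.3, 0.05), function(ns) {
    stat <- data.frame(probe_id = rel$probe_id,
                       value = icc + rnorm(400, sd = ns))
    associate_external(rel, stat, "spearman")$correlation
  }, 0)
  expect_true(all(rho > 0))
  expect_true(all(diff(rho) > 0))
})

test_that("concordance bins partition probes with boundaries in the lower bin", {
  rel <- rel_from(seq(0.01, 0.99, length.out = 9))
  stat <- data.frame(probe_id = rel$probe_id,
                     value = c(0.1, 0.4, 0.41, 0.5, 0.75, 0.76, 0.9, 0.2, 0.8))
  bins <- associate_external(rel, stat)$bins
  expect_equal(sum(bins$n), 9)
  expect_equal(bins$n[bins$bin == "low"], 3)   # 0.1, 0.4, 0.2 (0.4 -> low)
  expect_equal(bins$n[bins$bin == "mid"], 3)   # 0.41, 0.5, 0.75
  expect_equal(bins$n[bins$bin == "high"], 3)
})

test_that("multi-region intersections collapse and vanish as constructed", {
  rel <- rel_from(seq(0.01, 0.99, length.out = 200))
  v <- seq(0, 1, length.out = 200)
  one <- data.frame(probe_id = rel$probe_id, value = v)
  same <- multi_region_intersection(list(one, one, one, one), rel)
  single_bins <- associate_external(rel, one)$bins
  expect_equal(same$all_high$n, single_bins$n[single_bins$bin == "high"])

  # disjoint highs across two regions -> empty intersection, not an error
  a <- data.frame(probe_id = rel$probe_id, value = ifelse(seq_len(200) <= 100, 0.9, 0.1))
  b <- data.frame(probe_id = rel$probe_id, value = ifelse(seq_len(200) <= 100, 0.1, 0.9))
  expect_equal(multi_region_intersection(list(a, b), rel)$all_high$n, 0)
})

test_that("a shared high-ICC core makes the all-high intersection most reliable", {
  set.seed(29)
  icc <- c(runif(50, 0.8, 0.95), runif(350, 0, 0.6))
  rel <- rel_from(icc)
  regions <- lapply(1:4, function(r) {
    v <- ifelse(seq_along(icc) <= 50, runif(400, 0.7, 1), runif(400, 0, 0.85))
    data.frame(probe_id = rel$probe_id, value = v)
  })
  out <- multi_region_intersection(regions, rel)
  single_meds <- vapply(regions, function(s) {
    b <- associate_external(rel, s)$bins
    b$median_icc[b$bin == "high"]
  }, 0)
  expect_gt(out$all_high$median_icc, max(single_meds))
})

test_that("methylation-expression correlation: exact links and type-I control", {
  sim <- simulate_reliability_panel(200, 60, seed = 41)
  beta <- sim$paired$first
  links <- data.frame(probe_id = rownames(beta$values),
                      unit_id = paste0("U", seq_len(200)))
  # affine coupling for the first link -> |r| = 1, minimal p
  expr <- generate_expression(beta, links, effect_probes = links$probe_id[1],
                              effect_size = 2, noise_sd = 1e-12, seed = 42)
  out <- methylation_expression_correlation(beta, expr, links, alpha = 1e-7)
  expect_equal(abs(out$r[1]), 1, tolerance = 1e-6)
  expect_true(out$significant[1])
  expect_false(any(out$significant[-1]))

  # pure-noise expression: significant fraction at alpha = 0.05 ~ binomial
  expr0 <- generate_expression(beta, links, effect_probes = character(0),
                               effect_size = 0, noise_sd = 1, seed = 43)
  out0 <- methylation_expression_correlation(beta, expr0, links, alpha = 0.05)
  expect_lt(sum(out0$significant), 200 * 0.05 + 3 * sqrt(200 * 0.05 * 0.95) + 1)

  # zero-variance unit is skipped with a flag
  expr_z <- expr; expr_z["U2", ] <- 1
  out_z <- methylation_expression_correlation(beta, expr_z, links)
  expect_identical(out_z$flag[out_z$unit_id == "U2"], "zero_variance")
  expect_error(
    methylation_expression_correlation(beta, expr[, 1:5], links),
    "fewer than 10")
})

test_that("expression effects on reliable probes lift the significant set's reliability", {
  sim <- simulate_reliability_panel(600, 150, seed = 47)
  tbl <- reliability_table(sim$paired)
  beta <- sim$paired$first
  links <- data.frame(probe_id = tbl$probe_id,
                      unit_id = paste0("U", seq_len(600)))
  hi_probes <- tbl$probe_id[order(-tbl$icc)][1:60]
  expr <- generate_expression(beta, links, effect_probes = hi_probes,
                              effect_size = 3, noise_sd = 0.3, seed = 48)
  out <- methylation_expression_correlation(beta, expr, links, alpha = 1e-4)
  sig <- attr(out, "significant_probes")
  expect_gt(length(sig), 10)
  expect_gt(set_summary(tbl, sig)$median_icc,
            attr(tbl, "summary")$median_icc)
})
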