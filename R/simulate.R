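#' Default true-ICC mixture
#'
#' Mixture over \[0,1) emulating the heavily zero-skewed per-probe
#' reliability distribution seen in between-array test-retest panels: a
#' point mass near zero, two Beta components for the low/mid body, and a
#' small high-reliability component. The default calibration targets a
#' sample median near 0.09, mean near 0.21, and roughly 6% of probes above
#' 0.75 (windows: median in \[0.05, 0.13\], mean in \[0.17, 0.25\],
#' P(>0.75) in \[0.04, 0.09\]).
#'
#' @return list with `weights` (summing to 1), `point_value` (location of
#'   the near-zero point mass), and `shapes` (Beta shape pairs for the
#'   `low`, `mid`, `high` components).
#' @export
default_icc_mixture <- function() {
  list(weights = c(point = 0.30, low = 0.45, mid = 0.18, high = 0.07),
       point_value = 0.01,
       shapes = list(low = c(1.1, 6), mid = c(2.5, 2.5), high = c(8, 2)))
}

#' Configuration for the synthetic paired-methylation generator
#'
#' The generator works on the logit scale: each probe has a latent true
#' score with per-probe mean `mu` and a per-probe total single-occasion SD
#' drawn from `sigma_range`, split into true-score and noise variance so
#' that the average-of-two-measurements ICC equals the probe's target
#' (`icc = s_T^2 / (s_T^2 + (s_c^2 + s_E^2)/2)`, with `s_c` the
#' platform/rater offset SD). Observed values are inverse-logit transformed,
#' so betas always lie in (0,1).
#'
#' @param n_probes,n_samples panel dimensions (defaults emulate a
#'   350-sample paired design).
#' @param icc_mixture mixture specification, see [default_icc_mixture()].
#' @param rater_offset_sd SD of the per-probe platform offset on the logit
#'   scale (default 0.05).
#' @param mu_logit_range range of per-probe means on the logit scale.
#' @param sigma_range range of per-probe total single-occasion SD on the
#'   logit scale.
#' @param icc_max truncation point for true ICCs (an ICC of 1 would require
#'   zero noise and is excluded).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_probes, n_samples = 350,
                             icc_mixture = default_icc_mixture(),
                             rater_offset_sd = 0.05,
                             mu_logit_range = c(-3, 3),
                             sigma_range = c(0.3, 1.0),
                             icc_max = 0.98) {
  stopifnot(n_probes >= 1, n_samples >= 3, rater_offset_sd >= 0,
            length(sigma_range) == 2, sigma_range[1] > 0,
            icc_max > 0, icc_max < 1)
  if (abs(sum(icc_mixture$weights) - 1) > 1e-8)
    stop_mr("mixture weights must sum to 1")
  # Feasibility: the noisiest-feasible probe (smallest sigma, largest icc)
  # must still leave nonnegative residual noise after the rater offset.
  V_min <- sigma_range[1]^2
  D_min <- V_min * (2 - 2 * icc_max) / (2 - icc_max)
  if (D_min < rater_offset_sd^2)
    stop_mr("infeasible configuration: rater_offset_sd too large for ",
            "icc_max and sigma_range (no residual noise variance left)")
  structure(list(n_probes = n_probes, n_samples = n_samples,
                 icc_mixture = icc_mixture,
                 rater_offset_sd = rater_offset_sd,
                 mu_logit_range = mu_logit_range,
                 sigma_range = sigma_range, icc_max = icc_max),
            class = "generator_config")
}

#' Draw true per-probe ICCs from the configured mixture
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return numeric vector of length `config$n_probes`, each in
#'   \[0, `icc_max`\].
#' @export
draw_true_iccs <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  mix <- config$icc_mixture
  n <- config$n_probes
  with_seed(seed, {
    comp <- sample(names(mix$weights), n, replace = TRUE, prob = mix$weights)
    x <- numeric(n)
    x[comp == "point"] <- mix$point_value
    for (nm in names(mix$shapes)) {
      idx <- comp == nm
      if (any(idx))
        x[idx] <- stats::rbeta(sum(idx), mix$shapes[[nm]][1], mix$shapes[[nm]][2])
    }
    pmin(x, config$icc_max)
  })
}

#' Generate a paired beta-value panel with known true ICCs
#'
#' Latent model per probe p, subject i, occasion j:
#' `y_pij = T_pi + c_pj + e_pij` with true score
#' `T_pi ~ N(mu_p, s_T^2)`, per-probe-and-occasion platform offset
#' `c_pj ~ N(0, rater_offset_sd^2)` and noise `e_pij ~ N(0, s_E^2)`;
#' `beta = inverse-logit(y)`. The variance split is chosen from each
#' probe's target ICC via the average-of-two-measurements identity, so the
#' logit-scale panel carries exactly the target reliability; the mild
#' attenuation introduced by the inverse-logit compression on the beta
#' scale is a property of the scale, not of the generator.
#'
#' @param config a [generator_config()].
#' @param true_iccs per-probe target ICCs (e.g. from [draw_true_iccs()]);
#'   length `config$n_probes`, all < 1.
#' @param seed integer seed.
#' @return list with `paired` (a `paired_beta`) and `truth` (data.frame
#'   `probe_id, true_icc, mu_logit, sigma_T, sigma_E, offset_1, offset_2`).
#' @export
generate_paired <- function(config, true_iccs, seed) {
  stopifnot(inherits(config, "generator_config"),
            length(true_iccs) == config$n_probes)
  if (any(true_iccs >= 1))
    stop_mr("true_icc = 1 requires zero noise and is not generatable")
  if (any(true_iccs < 0)) stop_mr("true ICCs must be nonnegative")
  np <- config$n_probes; ns <- config$n_samples
  pid <- sprintf("P%06d", seq_len(np))
  sid <- sprintf("S%04d", seq_len(ns))
  sc2 <- config$rater_offset_sd^2
  with_seed(seed, {
    s <- stats::runif(np, config$sigma_range[1], config$sigma_range[2])
    V <- s^2
    t <- true_iccs * V / (2 - true_iccs)      # true-score variance
    D <- V - t                                # total disagreement variance
    sigE2 <- D - sc2
    if (any(sigE2 < -1e-12))
      stop_mr("infeasible true ICC for the configured rater offset")
    sigE <- sqrt(pmax(sigE2, 0))
    mu <- stats::runif(np, config$mu_logit_range[1], config$mu_logit_range[2])
    offs <- matrix(stats::rnorm(np * 2, 0, config$rater_offset_sd), np, 2)
    Tm <- mu + sqrt(t) * matrix(stats::rnorm(np * ns), np, ns)
    y1 <- Tm + offs[, 1] + sigE * matrix(stats::rnorm(np * ns), np, ns)
    y2 <- Tm + offs[, 2] + sigE * matrix(stats::rnorm(np * ns), np, ns)
    dimnames(y1) <- dimnames(y2) <- list(pid, sid)
    a <- beta_matrix(inv_logit(y1), "platform_A")
    b <- beta_matrix(inv_logit(y2), "platform_B")
    list(paired = pair_matrices(a, b),
         truth = data.frame(probe_id = pid, true_icc = true_iccs,
                            mu_logit = mu, sigma_T = sqrt(t), sigma_E = sigE,
                            offset_1 = offs[, 1], offset_2 = offs[, 2],
                            stringsAsFactors = FALSE))
  })
}

#' Convenience: calibrated paired panel in one call
#' @inheritParams generate_paired
#' @param n_probes,n_samples panel dimensions.
#' @param config optional [generator_config()]; defaults to the calibrated
#'   mixture with the given dimensions.
#' @return as [generate_paired()], plus the `config` used.
#' @export
simulate_reliability_panel <- function(n_probes, n_samples = 350, seed,
                                       config = NULL) {
  if (is.null(config)) config <- generator_config(n_probes, n_samples)
  iccs <- draw_true_iccs(config, seed = child_seed(seed, 1))
  out <- generate_paired(config, iccs, seed = child_seed(seed, 2))
  out$config <- config
  out
}

#' Generate a twin panel with known variance components
#'
#' Twin values follow `sqrt(a2) A + sqrt(c2) C + sqrt(e2) E` with the
#' additive-genetic factor correlated 1 between MZ co-twins and 0.5 between
#' DZ co-twins, the shared-environment factor correlated 1 in both, and the
#' unique-environment factor independent. With
#' `measurement_error = TRUE`, a per-probe noise term whose variance grows
#' as the probe's paired-design true ICC falls
#' (`sigma_m^2 = error_scale * (1 - icc)/(icc + 0.5)`) is added to every
#' twin value; it loads entirely on E, so unreliable probes end up suffused
#' with unique-environment variance — the coupling between reliability and
#' heritability estimates that the analysis quantifies.
#'
#' @param a2,c2,e2 per-probe variance proportions (each a vector, rows of a
#'   simplex; `e2` strictly positive).
#' @param n_mz,n_dz pair counts.
#' @param probe_ids optional probe ids (default `P000001...`).
#' @param measurement_error add the reliability-coupled noise term.
#' @param true_iccs per-probe true ICCs, required when
#'   `measurement_error = TRUE`.
#' @param error_scale scale of the coupled noise variance (default 1).
#' @param seed integer seed.
#' @return list with `panel` (matrices `mz1, mz2, dz1, dz2`, probes x
#'   pairs) and `truth` (input and realized components per probe;
#'   realized components fold the added noise into E).
#' @export
generate_twins <- function(a2, c2, e2, n_mz, n_dz, probe_ids = NULL,
                           measurement_error = FALSE, true_iccs = NULL,
                           error_scale = 1, seed) {
  np <- length(a2)
  stopifnot(length(c2) == np, length(e2) == np, n_mz >= 2, n_dz >= 2)
  if (any(abs(a2 + c2 + e2 - 1) > 1e-8))
    stop_mr("a2 + c2 + e2 must equal 1 for every probe")
  if (any(a2 < 0 | c2 < 0) || any(e2 <= 0))
    stop_mr("components must be nonnegative and e2 strictly positive")
  if (measurement_error && is.null(true_iccs))
    stop_mr("measurement_error = TRUE requires `true_iccs`")
  if (is.null(probe_ids)) probe_ids <- sprintf("P%06d", seq_len(np))
  with_seed(seed, {
    rn <- function(nc) matrix(stats::rnorm(np * nc), np, nc)
    sa <- sqrt(a2); sc <- sqrt(c2); se <- sqrt(e2)
    # MZ: shared A and C
    A <- rn(n_mz); C <- rn(n_mz)
    mz1 <- sa * A + sc * C + se * rn(n_mz)
    mz2 <- sa * A + sc * C + se * rn(n_mz)
    # DZ: A correlated 0.5 across co-twins, C shared
    A1 <- rn(n_dz); A2 <- 0.5 * A1 + sqrt(0.75) * rn(n_dz); Cd <- rn(n_dz)
    dz1 <- sa * A1 + sc * Cd + se * rn(n_dz)
    dz2 <- sa * A2 + sc * Cd + se * rn(n_dz)
    sig_m2 <- rep(0, np)
    if (measurement_error) {
      sig_m2 <- error_scale * (1 - true_iccs) / (true_iccs + 0.5)
      sm <- sqrt(sig_m2)
      mz1 <- mz1 + sm * rn(n_mz); mz2 <- mz2 + sm * rn(n_mz)
      dz1 <- dz1 + sm * rn(n_dz); dz2 <- dz2 + sm * rn(n_dz)
    }
    tot <- 1 + sig_m2
    panel <- list(mz1 = mz1, mz2 = mz2, dz1 = dz1, dz2 = dz2)
    panel <- lapply(panel, function(m) { rownames(m) <- probe_ids; m })
    list(panel = panel,
         truth = data.frame(
           probe_id = probe_ids, a2 = a2, c2 = c2, e2 = e2,
           sigma_m2 = sig_m2,
           a2_realized = a2 / tot, c2_realized = c2 / tot,
           e2_realized = (e2 + sig_m2) / tot,
           stringsAsFactors = FALSE))
  })
}

#' Generate reliability-coupled EWAS study hit lists
#'
#' A designated subset of effect probes is detected by each simulated study
#' with probability given by a monotone coupling of the probe's true ICC —
#' reliable probes replicate across studies, unreliable ones drop in and
#' out. Each effect probe has a fixed direction of effect, flipped per study
#' with a small probability; non-effect probes enter lists at a
#' false-positive rate with random direction.
#'
#' @param true_iccs per-probe true ICCs.
#' @param probe_ids aligned probe ids.
#' @param effect_probes character vector of effect-probe ids
#'   (subset of `probe_ids`).
#' @param n_studies number of studies (default 22).
#' @param base_detect baseline detection probability in (0,1).
#' @param coupling `"logistic"`, `"linear"`, `"step"`, `"constant"`
#'   (the null: detection independent of reliability), or a function
#'   mapping ICC to detection probability.
#' @param flip_prob per-study probability of flipping an effect probe's
#'   direction (default 0.05).
#' @param fp_rate per-study listing probability for non-effect probes.
#' @param seed integer seed.
#' @return data.frame `study_id, probe_id, direction` (all studies stacked),
#'   with the per-probe true direction attached as attribute
#'   `"true_direction"`.
#' @export
generate_study_hits <- function(true_iccs, probe_ids, effect_probes,
                                n_studies = 22, base_detect = 0.2,
                                coupling = "logistic", flip_prob = 0.05,
                                fp_rate = 0.001, seed) {
  stopifnot(length(true_iccs) == length(probe_ids),
            base_detect > 0, base_detect < 1,
            all(effect_probes %in% probe_ids))
  cap <- 0.95
  f <- if (is.function(coupling)) coupling else switch(
    coupling,
    constant = function(icc) rep(base_detect, length(icc)),
    logistic = function(icc) base_detect +
      (cap - base_detect) * stats::plogis((icc - 0.5) / 0.15),
    linear   = function(icc) base_detect + (cap - base_detect) * icc,
    step     = function(icc) base_detect + (cap - base_detect) * (icc > 0.5),
    stop_mr("unknown coupling: ", coupling))
  idx <- match(effect_probes, probe_ids)
  p_detect <- pmin(pmax(f(true_iccs[idx]), 0), 1)
  non_effect <- setdiff(probe_ids, effect_probes)
  with_seed(seed, {
    true_dir <- sample(c("up", "down"), length(effect_probes), replace = TRUE)
    rows <- lapply(seq_len(n_studies), function(s) {
      det <- stats::runif(length(effect_probes)) < p_detect
      flip <- stats::runif(length(effect_probes)) < flip_prob
      dir <- ifelse(flip, ifelse(true_dir == "up", "down", "up"), true_dir)
      fp <- non_effect[stats::runif(length(non_effect)) < fp_rate]
      data.frame(
        study_id = sprintf("study_%02d", s),
        probe_id = c(effect_probes[det], fp),
        direction = c(dir[det],
                      sample(c("up", "down"), length(fp), replace = TRUE)),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "true_direction") <- stats::setNames(true_dir, effect_probes)
    out
  })
}

#' Generate TSS-linked expression data coupled to methylation
#'
#' Expression of a unit linked to an effect probe is
#' `effect_size * beta_probe + N(0, noise_sd^2)` across samples; all other
#' units are pure noise. Units linked to several probes use the first link.
#'
#' @param beta a [beta_matrix()].
#' @param links data.frame `probe_id, unit_id`.
#' @param effect_probes probe ids whose linked units carry signal.
#' @param effect_size linear effect of beta on expression (default 1).
#' @param noise_sd residual SD (default 1).
#' @param seed integer seed.
#' @return numeric matrix, units x samples.
#' @export
generate_expression <- function(beta, links, effect_probes,
                                effect_size = 1, noise_sd = 1, seed) {
  stopifnot(inherits(beta, "beta_matrix"),
            all(effect_probes %in% links$probe_id))
  links <- links[!duplicated(links$unit_id), , drop = FALSE]
  units <- links$unit_id
  ns <- ncol(beta$values)
  with_seed(seed, {
    E <- matrix(stats::rnorm(length(units) * ns, 0, noise_sd),
                length(units), ns,
                dimnames = list(units, colnames(beta$values)))
    eff <- links$probe_id %in% effect_probes
    if (any(eff))
      E[eff, ] <- E[eff, , drop = FALSE] +
        effect_size * beta$values[links$probe_id[eff], , drop = FALSE]
    E
  })
}
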