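#' Construct a twin dataset for one trait (probe)
#'
#' @param mz,dz numeric matrices with two columns (twin 1, twin 2), one row
#'   per pair, for monozygotic and dizygotic pairs respectively.
#' @return object of class `twin_dataset`.
#' @export
twin_dataset <- function(mz, dz) {
  mz <- as.matrix(mz); dz <- as.matrix(dz)
  if (ncol(mz) != 2 || ncol(dz) != 2)
    stop_mr("`mz` and `dz` must each have 2 columns (one per co-twin)")
  mz <- mz[stats::complete.cases(mz), , drop = FALSE]
  dz <- dz[stats::complete.cases(dz), , drop = FALSE]
  structure(list(mz = mz, dz = dz, n_mz = nrow(mz), n_dz = nrow(dz)),
            class = "twin_dataset")
}

# Symmetric sufficient statistics of a standardized twin group: the
# bivariate-normal log-likelihood depends on the pairs only through
# n, S11 = sum(y1^2 + y2^2), S12 = sum(y1 * y2) — symmetric under
# swapping co-twins, so twin ordering is irrelevant by construction.
twin_suffstats <- function(y) {
  list(n = nrow(y), S11 = sum(y^2), S12 = sum(y[, 1] * y[, 2]))
}

# Log-likelihood of one zygosity group under correlation r (unit variances,
# zero means).
loglik_group <- function(ss, r) {
  -ss$n * log(2 * pi) - ss$n / 2 * log(1 - r^2) -
    (ss$S11 - 2 * r * ss$S12) / (2 * (1 - r^2))
}

#' ACE log-likelihood at given variance proportions
#'
#' Audit helper: the bivariate-normal log-likelihood of a (standardized)
#' twin dataset under twin-pair correlations `r_MZ = a2 + c2`,
#' `r_DZ = a2/2 + c2`, unit total variance.
#'
#' @param data a [twin_dataset()] (standardized internally as in
#'   [fit_ace_ml()]).
#' @param a2,c2,e2 variance proportions (must be a simplex).
#' @return log-likelihood value.
#' @export
ace_loglik <- function(data, a2, c2, e2) {
  stopifnot(inherits(data, "twin_dataset"))
  if (abs(a2 + c2 + e2 - 1) > 1e-6 || min(a2, c2, e2) < -1e-12)
    stop_mr("a2, c2, e2 must be nonnegative and sum to 1")
  std <- standardize_twins(data)
  loglik_group(twin_suffstats(std$mz), min(a2 + c2, 1 - 1e-10)) +
    loglik_group(twin_suffstats(std$dz), min(a2 / 2 + c2, 1 - 1e-10))
}

standardize_twins <- function(data) {
  all_v <- c(data$mz, data$dz)
  m <- mean(all_v); s <- stats::sd(all_v)
  if (s == 0) stop_mr("zero variance across twin values; cannot standardize")
  list(mz = (data$mz - m) / s, dz = (data$dz - m) / s)
}

#' Falconer closed-form ACE estimates from twin correlations
#'
#' Classical closed form: a2 = 2(r_MZ - r_DZ), c2 = 2 r_DZ - r_MZ,
#' e2 = 1 - r_MZ. Negative raw components are truncated at zero and the
#' remainder renormalized to sum to one.
#'
#' @param r_mz,r_dz twin-pair correlations in \[-1,1\].
#' @return list with `a2`, `c2`, `e2`, `loglik` (`NA`), `converged`,
#'   `method = "falconer"`, and a `boundary` flag marking truncation.
#' @export
fit_ace_falconer <- function(r_mz, r_dz) {
  stopifnot(abs(r_mz) <= 1, abs(r_dz) <= 1)
  raw <- c(a2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz, e2 = 1 - r_mz)
  boundary <- any(raw <= 0)
  raw[raw < 0] <- 0
  if (sum(raw) == 0) raw["e2"] <- 1
  p <- raw / sum(raw)
  list(a2 = unname(p["a2"]), c2 = unname(p["c2"]), e2 = unname(p["e2"]),
       loglik = NA_real_, converged = TRUE, method = "falconer",
       boundary = boundary)
}

#' Maximum-likelihood ACE decomposition of a twin trait
#'
#' Decomposes the variance of a standardized trait into additive-genetic
#' (A), shared-environmental (C) and unique-environmental (E) proportions by
#' maximizing the bivariate-normal log-likelihood of MZ and DZ twin pairs
#' with model correlations `r_MZ = a2 + c2`, `r_DZ = a2/2 + c2` and unit
#' total variance. Additive genetic effects are assumed perfectly correlated
#' in MZ pairs and 50% correlated in DZ pairs; shared environment is fully
#' correlated in both. Components are constrained nonnegative; boundary
#' solutions (a2 = 0 or c2 = 0) are permitted and flagged. The likelihood is
#' written on symmetric sufficient statistics, so co-twin ordering cannot
#' change the fit, and standardization makes estimates invariant to affine
#' transformation of the trait.
#'
#' The optimizer is bounded quasi-Newton (L-BFGS-B) from 3 fixed starts with
#' convergence tolerance 1e-8 on the log-likelihood; if all starts fail, the
#' Falconer closed form on the sample correlations is returned with
#' `converged = FALSE`.
#'
#' @param data a [twin_dataset()]; needs >= 2 MZ and >= 2 DZ pairs.
#' @param standardize center/scale values before fitting (default `TRUE`).
#' @return list with `a2`, `c2`, `e2`, `loglik`, `converged`, `method`
#'   (`"ml"` or `"falconer"` fallback), `boundary` flag.
#' @export
fit_ace_ml <- function(data, standardize = TRUE) {
  stopifnot(inherits(data, "twin_dataset"))
  if (data$n_mz < 2 || data$n_dz < 2)
    stop_mr("need at least 2 MZ and 2 DZ complete pairs")
  std <- if (standardize) standardize_twins(data) else list(mz = data$mz, dz = data$dz)
  ss_mz <- twin_suffstats(std$mz)
  ss_dz <- twin_suffstats(std$dz)

  # Triangular map from the unit box to the simplex:
  # a2 = x1, c2 = (1 - x1) * x2, e2 = (1 - x1) * (1 - x2).
  negll <- function(x) {
    a2 <- x[1]; c2 <- (1 - x[1]) * x[2]
    r_mz <- min(a2 + c2, 1 - 1e-10)
    r_dz <- a2 / 2 + c2
    -(loglik_group(ss_mz, r_mz) + loglik_group(ss_dz, r_dz))
  }
  eps <- 1e-9
  starts <- list(c(0.3, 0.3), c(0.6, 0.25), c(0.05, 0.6))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = c(eps, eps), upper = c(1 - 1e-4, 1 - eps),
                   control = list(factr = 1e-8 / .Machine$double.eps)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    fb <- fit_ace_falconer(stats::cor(std$mz)[1, 2], stats::cor(std$dz)[1, 2])
    fb$converged <- FALSE
    return(fb)
  }
  a2 <- best$par[1]; c2 <- (1 - best$par[1]) * best$par[2]
  e2 <- 1 - a2 - c2
  tol0 <- 1e-4
  list(a2 = a2, c2 = c2, e2 = e2,
       loglik = -best$value,
       converged = best$convergence == 0,
       method = "ml",
       boundary = (a2 < tol0 || c2 < tol0))
}

#' Per-probe ACE decomposition over a twin panel
#'
#' @param panel list with probes-by-pairs matrices `mz1`, `mz2`, `dz1`,
#'   `dz2` (co-twin 1 and 2 values per zygosity), as produced by
#'   [generate_twins()], with probe ids as rownames.
#' @return data.frame `probe_id, a2, c2, e2, loglik, converged, method`.
#' @export
ace_table <- function(panel) {
  stopifnot(all(c("mz1", "mz2", "dz1", "dz2") %in% names(panel)))
  pids <- rownames(panel$mz1)
  fits <- lapply(seq_along(pids), function(i) {
    d <- twin_dataset(cbind(panel$mz1[i, ], panel$mz2[i, ]),
                      cbind(panel$dz1[i, ], panel$dz2[i, ]))
    fit_ace_ml(d)
  })
  data.frame(
    probe_id = pids,
    a2 = vapply(fits, `[[`, 0, "a2"),
    c2 = vapply(fits, `[[`, 0, "c2"),
    e2 = vapply(fits, `[[`, 0, "e2"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    converged = vapply(fits, `[[`, TRUE, "converged"),
    method = vapply(fits, `[[`, "", "method"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate probe reliability with ACE variance components
#'
#' @param ace_tbl output of [ace_table()].
#' @param rel_tbl output of [reliability_table()].
#' @return list with Pearson correlations `r_a2`, `r_c2`, `r_e2` of ICC with
#'   each component across shared probes, and `n` shared probes.
#' @export
ace_reliability_association <- function(ace_tbl, rel_tbl) {
  m <- merge(ace_tbl, rel_tbl[, c("probe_id", "icc")], by = "probe_id")
  m <- m[!is.na(m$icc), ]
  if (nrow(m) < 3) stop_mr("fewer than 3 shared probes with defined ICC")
  safe_cor <- function(x, y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  list(r_a2 = safe_cor(m$icc, m$a2),
       r_c2 = safe_cor(m$icc, m$c2),
       r_e2 = safe_cor(m$icc, m$e2),
       n = nrow(m))
}
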