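#' Intraclass correlation for average of two measurements, absolute agreement
#'
#' Computes the two-way random-effects, absolute-agreement intraclass
#' correlation for the mean of k = 2 raters (McGraw & Wong's ICC(A,k)), the
#' model used throughout this package to quantify test-retest reliability of
#' a probe measured on two platforms. From the two-way ANOVA mean squares
#' (MSR between subjects, MSC between raters, MSE residual):
#'
#'   ICC(A,2) = (MSR - MSE) / (MSR + (MSC - MSE) / n)
#'
#' Absolute agreement penalizes a systematic offset between the two
#' measurement occasions (through MSC), which a Pearson correlation does not.
#' Negative estimates are reported as computed, never truncated at zero.
#'
#' @param x numeric n x 2 matrix: n subjects (paired samples) by 2
#'   measurement occasions. Rows with any `NA` are dropped (complete pairs).
#' @return list with `icc`, `n`, `k`, the mean squares `MSR`, `MSC`, `MSE`,
#'   and `flag` (`"ok"`, `"insufficient_n"` for n < 3, `"degenerate"` for
#'   zero total variance).
#' @seealso [reliability_table()] for the vectorized per-probe version.
#' @export
compute_icc_ak <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) != 2) stop_mr("`x` must have exactly 2 columns (k = 2 raters)")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  out <- list(icc = NA_real_, n = n, k = 2L,
              MSR = NA_real_, MSC = NA_real_, MSE = NA_real_, flag = "ok")
  if (n < 3) { out$flag <- "insufficient_n"; return(out) }
  g <- mean(x)
  sst <- sum((x - g)^2)
  if (sst == 0) { out$flag <- "degenerate"; return(out) }
  rm_ <- rowMeans(x)
  cm <- colMeans(x)
  ssr <- 2 * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sse <- sst - ssr - ssc
  out$MSR <- ssr / (n - 1)
  out$MSC <- ssc            # k - 1 = 1
  out$MSE <- max(sse, 0) / ((n - 1) * 1)
  out$icc <- (out$MSR - out$MSE) / (out$MSR + (out$MSC - out$MSE) / n)
  out
}

#' Pearson correlation between the two measurement occasions of one probe
#'
#' @param x numeric n x 2 matrix (complete pairs used).
#' @return list with `r`, `n`, `flag` (`"zero_variance"` when either column
#'   is constant, `"insufficient_n"` when n < 3).
#' @export
compute_pearson <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 3) return(list(r = NA_real_, n = n, flag = "insufficient_n"))
  if (stats::sd(x[, 1]) == 0 || stats::sd(x[, 2]) == 0)
    return(list(r = NA_real_, n = n, flag = "zero_variance"))
  list(r = stats::cor(x[, 1], x[, 2]), n = n, flag = "ok")
}

# Vectorized ICC(A,2) + Pearson across probes. A, B: probes x samples
# matrices with identical dimnames. Complete pairs per probe.
icc_vec <- function(A, B) {
  ok <- !is.na(A) & !is.na(B)
  A2 <- A; B2 <- B
  A2[!ok] <- 0; B2[!ok] <- 0
  n <- rowSums(ok)
  sa <- rowSums(A2); sb <- rowSums(B2)
  g <- (sa + sb) / (2 * n)
  saa <- rowSums(A2^2); sbb <- rowSums(B2^2); sab <- rowSums(A2 * B2)
  sst <- saa + sbb - 2 * n * g^2
  # row (subject) means m_i = (a_i + b_i)/2; SSR = 2 * sum (m_i - g)^2
  ssr <- 2 * ((saa + sbb + 2 * sab) / 4 - n * g^2)
  # column (rater) means; SSC = n/2 * (abar - bbar)^2
  ssc <- (sa - sb)^2 / (2 * n)
  sse <- pmax(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc
  mse <- sse / (n - 1)
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  # Pearson
  va <- saa - sa^2 / n
  vb <- sbb - sb^2 / n
  cab <- sab - sa * sb / n
  r <- cab / sqrt(va * vb)
  flag <- rep("ok", nrow(A))
  flag[sst <= 0] <- "degenerate"
  flag[n < 3] <- "insufficient_n"
  bad <- flag != "ok"
  icc[bad] <- NA_real_
  r[bad | va <= 0 | vb <= 0] <- NA_real_
  list(icc = icc, pearson_r = r, n = n,
       MSR = msr, MSC = msc, MSE = mse, flag = flag)
}

#' Per-probe reliability table for a paired beta matrix
#'
#' One row per probe with the ICC(A,2), Pearson r, summary statistics of the
#' first (reference) matrix, and the conventional reliability category.
#' Degenerate probes (zero variance) and probes with fewer than 3 complete
#' pairs are flagged, never fatal.
#'
#' @param paired a `paired_beta` object from [pair_matrices()].
#' @return data.frame with columns `probe_id`, `icc`, `pearson_r`,
#'   `mean_beta`, `sd_beta` (computed over the first matrix's samples),
#'   `n_pairs`, `category`, `flag`; the distribution summary from
#'   [reliability_summary()] is attached as attribute `"summary"`.
#' @export
reliability_table <- function(paired) {
  stopifnot(inherits(paired, "paired_beta"))
  A <- paired$first$values; B <- paired$second$values
  v <- icc_vec(A, B)
  tbl <- data.frame(
    probe_id  = rownames(A),
    icc       = v$icc,
    pearson_r = v$pearson_r,
    mean_beta = rowMeans(A, na.rm = TRUE),
    sd_beta   = apply(A, 1, stats::sd, na.rm = TRUE),
    n_pairs   = v$n,
    category  = classify_reliability(v$icc),
    flag      = v$flag,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(tbl, "summary") <- reliability_summary(tbl)
  tbl
}

#' Distribution summary of a reliability table
#' @param tbl output of [reliability_table()].
#' @return list with mean/median/min/max ICC (over defined values), probe
#'   counts per category, the proportion of probes with ICC > 0.75, and the
#'   number of flagged probes.
#' @export
reliability_summary <- function(tbl) {
  icc <- tbl$icc[!is.na(tbl$icc)]
  list(
    n_probes = nrow(tbl),
    n_defined = length(icc),
    mean_icc = mean(icc), median_icc = stats::median(icc),
    min_icc = if (length(icc)) min(icc) else NA_real_,
    max_icc = if (length(icc)) max(icc) else NA_real_,
    prop_excellent = mean(icc > 0.75),
    category_counts = as.list(table(factor(
      tbl$category, levels = c("poor", "fair", "good", "excellent")))),
    n_flagged = sum(tbl$flag != "ok"))
}

#' Classify reliability by conventional ICC bands
#'
#' `poor` below 0.4 (including negative estimates), `fair` in \[0.4, 0.6),
#' `good` in \[0.6, 0.75\], `excellent` above 0.75.
#'
#' @param icc numeric vector of ICC estimates (`NA` allowed).
#' @return character vector of categories (`NA` where `icc` is `NA`).
#' @export
classify_reliability <- function(icc) {
  out <- rep(NA_character_, length(icc))
  out[!is.na(icc) & icc < 0.4] <- "poor"
  out[!is.na(icc) & icc >= 0.4 & icc < 0.6] <- "fair"
  out[!is.na(icc) & icc >= 0.6 & icc <= 0.75] <- "good"
  out[!is.na(icc) & icc > 0.75] <- "excellent"
  out
}

#' Beta-value to M-value transform
#'
#' M = log2(beta / (1 - beta)), the standard variance-stabilizing transform
#' for skewed methylation proportions. A small offset `epsilon` is applied
#' only at the boundary values beta = 0 and beta = 1, where the ratio is
#' otherwise undefined; interior values are transformed exactly.
#'
#' @param beta numeric vector in \[0,1\].
#' @param epsilon boundary offset, default `1e-6`.
#' @return numeric vector of M values.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop_mr("beta values must lie in [0,1]")
  stopifnot(epsilon > 0)
  b <- beta
  at0 <- !is.na(b) & b == 0; at1 <- !is.na(b) & b == 1
  num <- b; den <- 1 - b
  num[at0] <- epsilon;       den[at0] <- 1 - b[at0] + epsilon
  num[at1] <- b[at1] + epsilon; den[at1] <- epsilon
  log2(num / den)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha familywise error rate, in (0,1).
#' @param n_tests number of tests (>= 1), e.g. the number of probes carried
#'   into an epigenome-wide analysis.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 438593)  # ~1.14e-7 for a full probe panel
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}
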