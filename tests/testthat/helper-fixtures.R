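# Shared builders for test fixtures; everything is generated in code.

make_beta <- function(values, probes = NULL, samples = NULL, platform = NA) {
  if (is.null(probes)) probes <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  beta_matrix(values, platform_label = platform)
}

rand_beta <- function(np, ns, seed) {
  set.seed(seed)
  make_beta(matrix(runif(np * ns), np, ns))
}

# Independent ICC(A,2) oracle: mean squares from a brute-force two-way
# ANOVA fit via stats::aov on the long-format data.
icc_aov_oracle <- function(x) {
  n <- nrow(x)
  d <- data.frame(y = c(x),
                  subj = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  a <- anova(aov(y ~ subj + rater, data = d))
  msr <- a["subj", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# Textbook product-moment formula, independent of stats::cor.
pearson_formula_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# Twin pairs whose sample correlation is exactly r: unit-variance,
# zero-mean, exactly orthogonal components.
exact_corr_pairs <- function(n, r, seed) {
  set.seed(seed)
  z <- as.vector(scale(rnorm(n)))
  e <- rnorm(n)
  e <- as.vector(scale(residuals(lm(e ~ z))))
  cbind(z, r * z + sqrt(1 - r^2) * e)
}

# Exhaustive running-sum oracle: walk the full ranking step by step.
es_bruteforce <- function(N, hit_pos, weights = NULL) {
  m <- length(hit_pos)
  if (is.null(weights)) weights <- rep(1, m)
  step <- rep(-1 / (N - m), N)
  step[hit_pos] <- weights / sum(weights)
  rs <- cumsum(step)
  ext <- c(max(rs), min(rs))
  ext[which.max(abs(ext))]
}
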