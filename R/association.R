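#' Relate probe reliability to an external per-probe statistic
#'
#' Correlates the ICC with any external statistic (published heritability,
#' blood-brain concordance, ...) across shared probes, and summarizes the
#' reliability distribution within the conventional statistic bins
#' low (<= 0.4), mid (0.4, 0.75] and high (> 0.75); boundary values fall in
#' the lower bin.
#'
#' @param rel_tbl output of [reliability_table()].
#' @param stat data.frame `probe_id, value` (see [read_external_stat()]).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `correlation`, `method`, `n`, `flag`, and `bins`: a
#'   data.frame `bin, n, median_icc, prop_excellent` partitioning all shared
#'   probes with a defined statistic.
#' @export
associate_external <- function(rel_tbl, stat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- merge(rel_tbl[, c("probe_id", "icc")], stat, by = "probe_id")
  m <- m[!is.na(m$icc) & !is.na(m$value), ]
  if (nrow(m) < 3) stop_mr("fewer than 3 shared probes with defined values")
  flag <- "ok"
  corr <- if (stats::sd(m$value) == 0 || stats::sd(m$icc) == 0) {
    flag <- "zero_variance"; NA_real_
  } else stats::cor(m$icc, m$value, method = method)
  bin <- cut(m$value, breaks = c(-Inf, 0.4, 0.75, Inf),
             labels = c("low", "mid", "high"), right = TRUE)
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    icc <- m$icc[bin == b]
    data.frame(bin = b, n = length(icc),
               median_icc = if (length(icc)) stats::median(icc) else NA_real_,
               prop_excellent = if (length(icc)) mean(icc > 0.75) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(correlation = corr, method = method, n = nrow(m), flag = flag, bins = bins)
}

#' Reliability of probes consistently high (or low) across regions
#'
#' Intersects per-region external statistics (e.g. blood-brain concordance
#' for four brain regions): probes above `high_cut` in every region and
#' probes below `low_cut` in every region, each summarized by median ICC and
#' proportion of probes with ICC > 0.75. Probes must have a defined
#' statistic in all regions to be considered. Empty intersections are
#' reported as empty, not errors.
#'
#' @param stats_list list (>= 2) of data.frames `probe_id, value`, one per
#'   region.
#' @param rel_tbl output of [reliability_table()].
#' @param high_cut,low_cut thresholds, defaults 0.75 and 0.4.
#' @return list with `all_high` and `all_low`, each a list
#'   `probe_ids, n, median_icc, prop_excellent`, plus `n_universe`.
#' @export
multi_region_intersection <- function(stats_list, rel_tbl,
                                      high_cut = 0.75, low_cut = 0.4) {
  stopifnot(length(stats_list) >= 2)
  complete <- Reduce(intersect, lapply(stats_list, function(s)
    s$probe_id[!is.na(s$value)]))
  vals <- lapply(stats_list, function(s)
    stats::setNames(s$value, s$probe_id)[complete])
  all_high <- complete[Reduce(`&`, lapply(vals, function(v) v > high_cut))]
  all_low  <- complete[Reduce(`&`, lapply(vals, function(v) v < low_cut))]
  summarize <- function(ids) {
    icc <- rel_tbl$icc[rel_tbl$probe_id %in% ids]
    icc <- icc[!is.na(icc)]
    list(probe_ids = ids, n = length(ids),
         median_icc = if (length(icc)) stats::median(icc) else NA_real_,
         prop_excellent = if (length(icc)) mean(icc > 0.75) else NA_real_)
  }
  list(all_high = summarize(all_high), all_low = summarize(all_low),
       n_universe = length(complete))
}

#' Correlate methylation with expression over TSS links
#'
#' For each probe-to-expression-unit link (a CpG localized to a gene's
#' transcription start site), computes the Pearson correlation between the
#' probe's beta values and the unit's expression values across shared
#' samples, with a two-sided p-value from the exact t transform on n - 2
#' degrees of freedom. Links involving a zero-variance probe or unit are
#' skipped with a flag.
#'
#' @param beta a [beta_matrix()].
#' @param expression numeric matrix, expression units in rows (rownames =
#'   unit ids), samples in columns (colnames shared with `beta`).
#' @param links data.frame `probe_id, unit_id` (deduplicated internally).
#' @param alpha significance level for flagging correlated links
#'   (default `1e-7`, the threshold used for TSS-level testing).
#' @return data.frame `probe_id, unit_id, r, p, n, significant, flag`, with
#'   the vector of significant probe ids attached as attribute
#'   `"significant_probes"`.
#' @export
methylation_expression_correlation <- function(beta, expression, links,
                                               alpha = 1e-7) {
  stopifnot(inherits(beta, "beta_matrix"))
  links <- unique(links[, c("probe_id", "unit_id")])
  if (nrow(links) == 0) stop_mr("no links supplied")
  shared <- intersect(colnames(beta$values), colnames(expression))
  if (length(shared) < 10) stop_mr("fewer than 10 shared samples")
  links <- links[links$probe_id %in% rownames(beta$values) &
                   links$unit_id %in% rownames(expression), , drop = FALSE]
  if (nrow(links) == 0) stop_mr("no links match the supplied matrices")
  B <- beta$values[links$probe_id, shared, drop = FALSE]
  E <- expression[links$unit_id, shared, drop = FALSE]
  n <- length(shared)
  sdB <- apply(B, 1, stats::sd); sdE <- apply(E, 1, stats::sd)
  zero <- sdB == 0 | sdE == 0
  r <- rep(NA_real_, nrow(links))
  Bc <- B - rowMeans(B); Ec <- E - rowMeans(E)
  r[!zero] <- rowSums(Bc * Ec)[!zero] /
    ((n - 1) * sdB[!zero] * sdE[!zero])
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  out <- data.frame(probe_id = links$probe_id, unit_id = links$unit_id,
                    r = r, p = p, n = n,
                    significant = !is.na(p) & p < alpha,
                    flag = ifelse(zero, "zero_variance", "ok"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "significant_probes") <- unique(out$probe_id[out$significant])
  out
}
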