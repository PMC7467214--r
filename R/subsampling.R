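#' Sensitivity of a reduced-replicate reliability screen
#'
#' How well does a screen run with only `n_replicates` paired samples
#' recover the reliable-probe set (ICC > `threshold`) identified by the full
#' panel? For each of `n_draws` draws, `n_replicates` pairs are sampled
#' without replacement, per-probe ICCs are recomputed, and probes exceeding
#' the threshold are compared with the full-panel flags. Probes that become
#' degenerate (or otherwise undefined) in a subsample are conservatively
#' counted as not flagged. Specificity (full-panel non-reliable probes also
#' not flagged in the subsample) is reported alongside.
#'
#' @param paired a `paired_beta` object.
#' @param n_replicates number of pairs per draw (< number of paired
#'   samples, or equal for the identity check).
#' @param threshold ICC cutpoint defining "reliable" (default 0.75).
#' @param n_draws number of independent draws (>= 10, default 100).
#' @param seed integer seed; deterministic given the seed.
#' @return list with `n_replicates`, `n_draws`, `seed`, `threshold`,
#'   `sensitivity` (mean over draws), `specificity`, `per_draw`
#'   (data.frame of per-draw values), `n_reference_reliable`, `flag`
#'   (`"no_reference_reliable"` when the full panel flags no probe, making
#'   sensitivity undefined).
#' @export
subsample_sensitivity <- function(paired, n_replicates, threshold = 0.75,
                                  n_draws = 100, seed) {
  stopifnot(inherits(paired, "paired_beta"), n_draws >= 10,
            threshold > 0, threshold < 1)
  A <- paired$first$values; B <- paired$second$values
  n_pairs <- ncol(A)
  if (n_replicates > n_pairs) stop_mr("n_replicates exceeds the number of paired samples")
  if (n_replicates < 3) stop_mr("need at least 3 replicates for an ICC")
  full <- icc_vec(A, B)
  ref <- !is.na(full$icc) & full$icc > threshold
  n_ref <- sum(ref)
  draws <- with_seed(seed, lapply(seq_len(n_draws), function(d)
    sample.int(n_pairs, n_replicates)))
  per <- vapply(draws, function(idx) {
    v <- icc_vec(A[, idx, drop = FALSE], B[, idx, drop = FALSE])
    flagged <- !is.na(v$icc) & v$icc > threshold
    c(sensitivity = if (n_ref > 0) sum(flagged & ref) / n_ref else NA_real_,
      specificity = if (n_ref < length(ref))
        sum(!flagged & !ref) / sum(!ref) else NA_real_)
  }, c(sensitivity = 0, specificity = 0))
  list(n_replicates = n_replicates, n_draws = n_draws, seed = seed,
       threshold = threshold,
       sensitivity = mean(per["sensitivity", ]),
       specificity = mean(per["specificity", ]),
       per_draw = data.frame(t(per)),
       n_reference_reliable = n_ref,
       flag = if (n_ref == 0) "no_reference_reliable" else "ok")
}

#' Sensitivity as a function of replicate count
#'
#' Runs [subsample_sensitivity()] over an ascending grid of replicate
#' counts (per-grid-point seeds derived from `seed`) and reports whether the
#' mean sensitivity is monotone nondecreasing along the grid — the expected
#' behavior, up to sampling noise, since more replicates estimate each ICC
#' more precisely.
#'
#' @inheritParams subsample_sensitivity
#' @param n_grid ascending vector of replicate counts.
#' @return data.frame with one row per grid point (`n_replicates`,
#'   `sensitivity`, `specificity`, `se_sensitivity`, `n_reference_reliable`),
#'   with the full per-point results as attribute `"results"` and a
#'   `"monotone"` attribute (logical).
#' @export
sensitivity_curve <- function(paired, n_grid, threshold = 0.75,
                              n_draws = 100, seed) {
  stopifnot(!is.unsorted(n_grid, strictly = TRUE))
  res <- lapply(seq_along(n_grid), function(i)
    subsample_sensitivity(paired, n_grid[i], threshold, n_draws,
                          seed = child_seed(seed, i)))
  out <- data.frame(
    n_replicates = n_grid,
    sensitivity = vapply(res, `[[`, 0, "sensitivity"),
    specificity = vapply(res, `[[`, 0, "specificity"),
    se_sensitivity = vapply(res, function(r)
      stats::sd(r$per_draw$sensitivity) / sqrt(r$n_draws), 0),
    n_reference_reliable = vapply(res, `[[`, 0L, "n_reference_reliable"))
  attr(out, "results") <- res
  attr(out, "monotone") <- !is.unsorted(out$sensitivity)
  out
}
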