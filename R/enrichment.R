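#' Rank probes by a statistic for enrichment testing
#'
#' Orders probes by descending statistic (by default the ICC from a
#' reliability table); ties are broken by probe-id lexicographic order so
#' the ranking is deterministic.
#'
#' @param probe_ids character vector of probe ids.
#' @param stats aligned numeric statistic (probes with `NA` are dropped).
#' @return object of class `ranked_probes`: list with ordered `probe_ids`
#'   and `stats`.
#' @export
rank_probes <- function(probe_ids, stats) {
  stopifnot(length(probe_ids) == length(stats))
  keep <- !is.na(stats)
  probe_ids <- as.character(probe_ids[keep]); stats <- stats[keep]
  if (anyDuplicated(probe_ids)) stop_mr("duplicate probe ids in ranking")
  o <- order(-stats, probe_ids)
  structure(list(probe_ids = probe_ids[o], stats = stats[o]),
            class = "ranked_probes")
}

#' Ranking from a reliability table
#' @param rel_tbl output of [reliability_table()].
#' @return a `ranked_probes` object ordered by descending ICC.
#' @export
rank_by_icc <- function(rel_tbl) rank_probes(rel_tbl$probe_id, rel_tbl$icc)

# Core running-sum extremum from sorted hit positions. Weighted
# Kolmogorov-Smirnov style: at a hit the sum rises by |stat|^w normalized
# over the in-set total; at a miss it falls by 1/(N - m). The extrema can
# only occur immediately at (after/before) hit positions, so the signed
# maximum deviation is computed in O(m).
es_from_positions <- function(pos, w_at_pos, N) {
  m <- length(pos)
  o <- order(pos)
  pos <- pos[o]; w <- w_at_pos[o]
  W <- sum(w)
  if (W == 0) w[] <- 1 / m else w <- w / W     # all-zero stats: unweighted
  miss <- 1 / (N - m)
  cumw <- cumsum(w)
  after  <- cumw - (pos - seq_len(m)) * miss           # just after each hit
  before <- c(0, cumw[-m]) - (pos - seq_len(m)) * miss # just before each hit
  hi <- max(after); lo <- min(c(before, 0))
  if (hi >= -lo) hi else lo
}

#' Weighted running-sum enrichment score of a probe set
#'
#' Computes the signed maximum deviation of the weighted Kolmogorov-Smirnov
#' running sum of `set` along the ranking: positive when set members
#' concentrate at the top (the reliable end when ranking by ICC).
#'
#' @param ranked a `ranked_probes` object.
#' @param set a [probe_set()] (ids absent from the ranking are ignored; the
#'   intersection must be non-empty and strictly smaller than the ranking).
#' @param weight_exponent exponent w applied to |statistic| at hits;
#'   default 1 (the usual weighted convention), 0 gives the classic
#'   unweighted statistic.
#' @param profile if `TRUE`, also return the length-N running-sum profile.
#' @return list with `es`, `set_size` (in-ranking hits), `hit_positions`,
#'   and optionally `profile`.
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1, profile = FALSE) {
  stopifnot(inherits(ranked, "ranked_probes"), weight_exponent >= 0)
  ids <- if (inherits(set, "probe_set")) set$probe_ids else as.character(set)
  N <- length(ranked$probe_ids)
  pos <- which(ranked$probe_ids %in% ids)
  if (length(pos) == 0)
    stop_mr("probe set has no overlap with the ranking (",
            length(ids), " ids, none present)")
  if (length(pos) == N)
    stop_mr("probe set covers the entire ranking; enrichment is undefined")
  wts <- abs(ranked$stats[pos])^weight_exponent
  es <- es_from_positions(pos, wts, N)
  out <- list(es = es, set_size = length(pos), hit_positions = pos)
  if (profile) {
    m <- length(pos)
    W <- sum(wts); step <- numeric(N)
    step[] <- -1 / (N - m)
    step[pos] <- if (W == 0) 1 / m else wts / W
    out$profile <- cumsum(step)
  }
  out
}

#' Permutation enrichment test of a probe set against a ranking
#'
#' Null enrichment scores come from random probe sets of the same size drawn
#' without replacement from the ranking (set permutation, as in preranked
#' enrichment analysis). The normalized score divides the observed score by
#' the mean absolute null score of matching sign, and the p-value uses the
#' add-one permutation convention, so its lower bound is
#' `1/(n_permutations + 1)`.
#'
#' @inheritParams enrichment_score
#' @param n_permutations number of null sets (>= 100; the analysis default
#'   is 10,000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return data.frame with one row: `set_name`, `set_size`, `es`, `nes`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
enrichment_test <- function(ranked, set, n_permutations = 10000, seed,
                            weight_exponent = 1) {
  stopifnot(n_permutations >= 100)
  obs <- enrichment_score(ranked, set, weight_exponent)
  N <- length(ranked$probe_ids)
  m <- obs$set_size
  absw <- abs(ranked$stats)^weight_exponent
  null_es <- with_seed(seed, vapply(seq_len(n_permutations), function(i) {
    p <- sample.int(N, m)
    es_from_positions(p, absw[p], N)
  }, 0))
  if (obs$es >= 0) {
    p_val <- (1 + sum(null_es >= obs$es)) / (n_permutations + 1)
    denom <- mean(abs(null_es[null_es >= 0]))
  } else {
    p_val <- (1 + sum(null_es <= obs$es)) / (n_permutations + 1)
    denom <- mean(abs(null_es[null_es < 0]))
  }
  nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
  data.frame(
    set_name = if (inherits(set, "probe_set")) set$name else NA_character_,
    set_size = m, es = obs$es, nes = nes, p_value = p_val,
    n_permutations = n_permutations, seed = seed,
    stringsAsFactors = FALSE)
}

#' Enrichment tests for several probe sets
#' @inheritParams enrichment_test
#' @param sets list of [probe_set()] objects.
#' @return data.frame, one row per set (seeds derived per set from `seed`).
#' @export
enrichment_table <- function(ranked, sets, n_permutations = 10000, seed,
                             weight_exponent = 1) {
  rows <- lapply(seq_along(sets), function(i)
    enrichment_test(ranked, sets[[i]], n_permutations,
                    seed = child_seed(seed, i), weight_exponent = weight_exponent))
  do.call(rbind, rows)
}

#' Reliability summary of a probe set
#'
#' The box-plot-style summary used when comparing a probe set (a clock, an
#' mQTL list, an expression-correlated set) against the background: median
#' ICC, interquartile range, and the proportion of set probes exceeding the
#' "excellent" threshold 0.75.
#'
#' @param rel_tbl output of [reliability_table()].
#' @param set a [probe_set()] or character vector of probe ids.
#' @return list with `set_name`, `n` (probes found with defined ICC),
#'   `median_icc`, `iqr_icc`, `q25`, `q75`, `prop_excellent`.
#' @export
set_summary <- function(rel_tbl, set) {
  ids <- if (inherits(set, "probe_set")) set$probe_ids else as.character(set)
  nm <- if (inherits(set, "probe_set")) set$name else NA_character_
  icc <- rel_tbl$icc[rel_tbl$probe_id %in% ids]
  icc <- icc[!is.na(icc)]
  if (length(icc) == 0) stop_mr("probe set has no overlap with the reliability table")
  q <- stats::quantile(icc, c(0.25, 0.75), names = FALSE)
  list(set_name = nm, n = length(icc),
       median_icc = stats::median(icc),
       q25 = q[1], q75 = q[2], iqr_icc = q[2] - q[1],
       prop_excellent = mean(icc > 0.75))
}
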