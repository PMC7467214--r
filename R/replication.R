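#' Tally direction-consistent replication of EWAS hits across studies
#'
#' For every probe reported significant in at least one study, counts how
#' many studies listed it and how many listed it with the majority direction
#' of effect. A probe reported "up" in 3 studies and "down" in 1 replicates
#' 3 times with majority direction up. Probes never listed anywhere do not
#' appear in the output.
#'
#' @param hits data.frame with columns `study_id`, `probe_id`, `direction`
#'   (`"up"`/`"down"`), e.g. from [read_study_hits()], covering >= 2 studies.
#' @param mixed_rule how to count a probe listed in both directions:
#'   `"majority"` (default) counts the majority-direction listings;
#'   `"zero"` counts mixed-direction probes as zero consistent replications.
#'   Exact ties always yield `majority_direction = "tie"` with
#'   `n_consistent` equal to the per-direction count (or 0 under `"zero"`).
#' @return data.frame `probe_id, n_studies_listed, n_consistent,
#'   majority_direction`.
#' @export
count_replications <- function(hits, mixed_rule = c("majority", "zero")) {
  mixed_rule <- match.arg(mixed_rule)
  need <- c("study_id", "probe_id", "direction")
  stopifnot(all(need %in% names(hits)))
  if (length(unique(hits$study_id)) < 2)
    stop_mr("need hit lists from at least 2 studies")
  hits$direction <- canonical_direction(hits$direction)
  dup <- duplicated(hits[, c("study_id", "probe_id")])
  if (any(dup))
    stop_mr("probe listed more than once within a study: ",
            paste(utils::head(unique(hits$probe_id[dup]), 5), collapse = ", "))
  pid <- factor(hits$probe_id)
  n_up <- as.vector(tapply(hits$direction == "up", pid, sum))
  n_down <- as.vector(tapply(hits$direction == "down", pid, sum))
  n_listed <- n_up + n_down
  maj <- ifelse(n_up > n_down, "up", ifelse(n_down > n_up, "down", "tie"))
  n_cons <- pmax(n_up, n_down)
  if (mixed_rule == "zero")
    n_cons[n_up > 0 & n_down > 0] <- 0L
  out <- data.frame(probe_id = levels(pid),
                    n_studies_listed = n_listed,
                    n_consistent = as.integer(n_cons),
                    majority_direction = maj,
                    stringsAsFactors = FALSE)
  out[order(out$probe_id), , drop = FALSE]
}

#' Relate replication counts to probe reliability
#'
#' Pearson correlation between the consistent-replication tally and the ICC
#' across the probes that were significant in at least one study, plus group
#' summaries for low-reliability (`icc < low_cut`) and high-reliability
#' (`icc > high_cut`) probes.
#'
#' @param counts output of [count_replications()].
#' @param rel_tbl output of [reliability_table()].
#' @param low_cut,high_cut ICC cutpoints for the group summaries
#'   (defaults 0.4 and 0.75, the "poor" and "excellent" boundaries).
#' @return list with `r`, `n`, `flag`, and `low`/`high` group summaries
#'   (mean, median, sd, n of the replication count); an empty group yields
#'   `NA` summaries with a flag.
#' @export
replication_reliability_association <- function(counts, rel_tbl,
                                                low_cut = 0.4, high_cut = 0.75) {
  m <- merge(counts, rel_tbl[, c("probe_id", "icc")], by = "probe_id")
  m <- m[!is.na(m$icc), ]
  if (nrow(m) < 3) stop_mr("fewer than 3 probes shared with the reliability table")
  flag <- "ok"
  r <- if (stats::sd(m$n_consistent) == 0 || stats::sd(m$icc) == 0) {
    flag <- "zero_variance"
    NA_real_
  } else stats::cor(m$n_consistent, m$icc)
  grp <- function(sel) {
    x <- m$n_consistent[sel]
    if (length(x) == 0)
      return(list(mean = NA_real_, median = NA_real_, sd = NA_real_,
                  n = 0L, flag = "empty_group"))
    list(mean = mean(x), median = stats::median(x), sd = stats::sd(x),
         n = length(x), flag = "ok")
  }
  list(r = r, n = nrow(m), flag = flag,
       low = grp(m$icc < low_cut), high = grp(m$icc > high_cut))
}

#' Replication-vs-reliability summary from published artifact files
#'
#' Convenience wrapper for reproducing a published replication analysis
#' from deposited files: a stacked study-hits TSV
#' (`study_id, probe_id, direction`) and a per-probe reliability TSV
#' (`probe_id, value` holding published ICCs).
#'
#' @param hits_path path to the study-hits TSV.
#' @param icc_path path to the per-probe ICC TSV.
#' @param ... passed to [replication_reliability_association()].
#' @return as [replication_reliability_association()].
#' @export
published_replication_summary <- function(hits_path, icc_path, ...) {
  hits <- read_study_hits(hits_path)
  icc <- read_external_stat(icc_path)
  rel <- data.frame(probe_id = icc$probe_id, icc = icc$value,
                    stringsAsFactors = FALSE)
  counts <- count_replications(hits)
  replication_reliability_association(counts, rel, ...)
}
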