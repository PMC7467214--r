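#' Construct a validated beta-value matrix
#'
#' A `beta_matrix` holds probe-by-sample methylation beta values (proportion
#' methylated, each in \[0,1\] or `NA`) from one measurement occasion /
#' platform. Probe ids are the rownames, sample ids the colnames; both must be
#' unique. Probe ids are treated as opaque strings, so synthetic ids work in
#' every downstream step.
#'
#' @param values numeric matrix, probes in rows, samples in columns, with
#'   rownames (probe ids) and colnames (sample ids).
#' @param platform_label free-text label for the measurement occasion
#'   (e.g. `"450K"`, `"EPIC"`).
#' @return object of class `beta_matrix`: a list with elements `values` and
#'   `platform_label`.
#' @export
beta_matrix <- function(values, platform_label = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_mr("`values` must be a numeric matrix")
  pid <- rownames(values); sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop_mr("`values` must have probe-id rownames and sample-id colnames")
  if (anyDuplicated(pid))
    stop_mr("duplicate probe ids: ", paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop_mr("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_mr(sprintf(
      "beta value out of [0,1]: probe '%s', sample '%s' (value %g)",
      pid[bad[1, 1]], sid[bad[1, 2]], values[bad[1, , drop = FALSE]]))
  }
  structure(list(values = values, platform_label = platform_label),
            class = "beta_matrix")
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d probes x %d samples (platform: %s)\n",
              nrow(x$values), ncol(x$values), x$platform_label))
  invisible(x)
}

#' Read a beta-value matrix from delimited text
#'
#' Expects a header row of sample ids and a first column named `probe_id`;
#' remaining cells are beta values in \[0,1\] or `NA`.
#'
#' @param path file path.
#' @param delimiter field delimiter, tab by default.
#' @param platform_label optional platform tag stored on the result.
#' @return a [beta_matrix()].
#' @export
read_beta_matrix <- function(path, delimiter = "\t", platform_label = NA_character_) {
  if (!file.exists(path)) stop_mr("file not found: ", path)
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          na.strings = "NA", data.table = FALSE)
  if (ncol(dt) < 2 || names(dt)[1] != "probe_id")
    stop_mr("first column must be `probe_id`: ", path)
  pid <- as.character(dt[[1]])
  if (anyDuplicated(pid))
    stop_mr("duplicate probe ids in ", path, ": ",
            paste(utils::head(unique(pid[duplicated(pid)]), 5), collapse = ", "))
  vals <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- pid
  beta_matrix(vals, platform_label = platform_label)
}

#' Write a beta-value matrix as TSV
#' @param x a [beta_matrix()].
#' @param path output path.
#' @export
write_beta_matrix <- function(x, path) {
  stopifnot(inherits(x, "beta_matrix"))
  dt <- data.table::data.table(probe_id = rownames(x$values))
  dt <- cbind(dt, data.table::as.data.table(x$values))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Pair two beta matrices measuring the same DNA
#'
#' Aligns two matrices (e.g. the same samples run on the 450K and EPIC
#' BeadChips) on their common probes and on a sample correspondence, yielding
#' the paired object every reliability computation consumes.
#'
#' @param a,b [beta_matrix()] objects for the two measurement occasions.
#' @param sample_map named character vector mapping sample ids of `a` to
#'   sample ids of `b`; defaults to the identity map on shared sample ids.
#' @return object of class `paired_beta`: list with `first`, `second`
#'   (probe- and sample-aligned `beta_matrix` objects), and a `dropped`
#'   report (probes/samples excluded from either side).
#' @export
pair_matrices <- function(a, b, sample_map = NULL) {
  stopifnot(inherits(a, "beta_matrix"), inherits(b, "beta_matrix"))
  if (is.null(sample_map)) {
    shared <- intersect(colnames(a$values), colnames(b$values))
    sample_map <- stats::setNames(shared, shared)
  }
  if (is.null(names(sample_map))) stop_mr("`sample_map` must be named (names = samples of `a`)")
  keep <- names(sample_map) %in% colnames(a$values) & sample_map %in% colnames(b$values)
  sample_map <- sample_map[keep]
  if (length(sample_map) == 0) stop_mr("no paired samples after mapping")
  if (anyDuplicated(sample_map) || anyDuplicated(names(sample_map)))
    stop_mr("`sample_map` must be one-to-one; duplicated source or target sample ids")
  probes <- intersect(rownames(a$values), rownames(b$values))
  if (length(probes) == 0) stop_mr("no probes shared between the two matrices")
  dropped <- list(
    probes_a  = setdiff(rownames(a$values), probes),
    probes_b  = setdiff(rownames(b$values), probes),
    samples_a = setdiff(colnames(a$values), names(sample_map)),
    samples_b = setdiff(colnames(b$values), unname(sample_map)))
  va <- a$values[probes, names(sample_map), drop = FALSE]
  vb <- b$values[probes, unname(sample_map), drop = FALSE]
  structure(list(
    first  = beta_matrix(va, a$platform_label),
    second = beta_matrix(vb, b$platform_label),
    sample_map = sample_map,
    dropped = dropped), class = "paired_beta")
}

#' @export
print.paired_beta <- function(x, ...) {
  cat(sprintf("paired_beta: %d probes x %d paired samples (%s vs %s)\n",
              nrow(x$first$values), ncol(x$first$values),
              x$first$platform_label, x$second$platform_label))
  invisible(x)
}

#' Read probe sets (plain list or GMT)
#'
#' Plain format: one probe id per line. GMT format: one set per line,
#' `name<TAB>description<TAB>id1<TAB>id2...`. Sets must be non-empty and ids
#' within a set unique.
#'
#' @param path file path.
#' @param format `"auto"` (GMT if any line has >= 3 tab-separated fields),
#'   `"plain"` or `"gmt"`.
#' @return named list of `probe_set` objects (`list(name, probe_ids)`).
#' @export
read_probe_sets <- function(path, format = c("auto", "plain", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mr("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop_mr("empty probe-set file: ", path)
  if (format == "auto") {
    format <- if (any(lengths(strsplit(lines, "\t", fixed = TRUE)) >= 3)) "gmt" else "plain"
  }
  if (format == "plain") {
    ids <- trimws(lines)
    sets <- list(probe_set(basename(path), ids))
  } else {
    sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
      if (length(f) < 3) stop_mr("malformed GMT line (need name, description, >=1 id)")
      probe_set(f[1], f[-(1:2)])
    })
  }
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Construct a probe set
#' @param name set name.
#' @param probe_ids character vector of probe ids (non-empty, unique).
#' @export
probe_set <- function(name, probe_ids) {
  probe_ids <- as.character(probe_ids)
  if (length(probe_ids) == 0) stop_mr("probe set '", name, "' is empty")
  if (anyDuplicated(probe_ids))
    stop_mr("probe set '", name, "' has duplicated ids")
  structure(list(name = as.character(name), probe_ids = probe_ids),
            class = "probe_set")
}

#' Write probe sets in GMT format
#' @param sets list of [probe_set()] objects.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, "na", s$probe_ids), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read per-study EWAS hit lists
#'
#' TSV with columns `study_id, probe_id, direction`. Direction tokens are
#' `up`/`down`, with `+`/`-` accepted as synonyms.
#'
#' @param path file path.
#' @return data.frame with columns `study_id`, `probe_id`, `direction`
#'   (canonicalized to `"up"`/`"down"`).
#' @export
read_study_hits <- function(path) {
  if (!file.exists(path)) stop_mr("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character")
  need <- c("study_id", "probe_id", "direction")
  if (!all(need %in% names(dt)))
    stop_mr("study-hits file must have columns: ", paste(need, collapse = ", "))
  dir <- canonical_direction(dt$direction)
  data.frame(study_id = dt$study_id, probe_id = dt$probe_id,
             direction = dir, stringsAsFactors = FALSE)
}

canonical_direction <- function(x) {
  map <- c(up = "up", down = "down", "+" = "up", "-" = "down")
  out <- map[tolower(trimws(x))]
  if (anyNA(out))
    stop_mr("invalid direction token(s): ",
            paste(unique(x[is.na(out)]), collapse = ", "),
            " (allowed: up, down, +, -)")
  unname(out)
}

#' Read an external per-probe statistic
#'
#' TSV with columns `probe_id, value` (e.g. blood-brain concordance
#' correlations, published heritability estimates). One row per probe.
#'
#' @param path file path.
#' @return data.frame with columns `probe_id`, `value`.
#' @export
read_external_stat <- function(path) {
  if (!file.exists(path)) stop_mr("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("probe_id", "value") %in% names(dt)))
    stop_mr("external-stat file must have columns: probe_id, value")
  if (anyDuplicated(dt$probe_id))
    stop_mr("duplicate probe ids in external-stat file: ", path)
  data.frame(probe_id = as.character(dt$probe_id),
             value = as.numeric(dt$value), stringsAsFactors = FALSE)
}

#' Write a data.frame as TSV
#' @param x data.frame. @param path output path.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
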