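#' Filter decoys, contaminants and sparsely identified proteins
#'
#' Removes rows flagged as reversed-sequence decoys or potential
#' contaminants, and rows quantified (non-missing) in fewer than
#' \code{min_identifications} runs across the whole data set. A flagged row
#' is removed regardless of how often it was observed. Counts removed by
#' each filter are recorded in the returned table's \code{filter_counts}
#' field. Filtering is idempotent.
#'
#' @param table a \code{\link{protein_quant_table}}.
#' @param min_identifications minimum number of runs a protein must be
#'   quantified in to be retained (default 3).
#' @return the filtered \code{ProteinQuantTable} with
#'   \code{filter_counts = list(reverse, contaminant, min_ident)}.
#' @export
filter_proteins <- function(table, min_identifications = 3) {
  stopifnot(inherits(table, "ProteinQuantTable"))
  if (min_identifications < 1) stop("min_identifications must be >= 1")
  n_obs <- rowSums(!is.na(table$intensities))
  drop_rev <- table$is_reverse
  drop_con <- !drop_rev & table$is_contaminant
  drop_min <- !drop_rev & !drop_con & n_obs < min_identifications
  keep <- !(drop_rev | drop_con | drop_min)
  out <- protein_quant_table(
    table$protein_id[keep],
    table$intensities[keep, , drop = FALSE],
    table$annotations,
    is_reverse = table$is_reverse[keep],
    is_contaminant = table$is_contaminant[keep]
  )
  out$filter_counts <- list(
    reverse = sum(drop_rev),
    contaminant = sum(drop_con),
    min_ident = sum(drop_min)
  )
  out
}

#' Impute missing intensities with a global epsilon pseudo-count
#'
#' Every missing cell is replaced by a single global value
#' epsilon = (minimum intensity observed in the entire data set) / 4,
#' on the raw intensity scale, before any log transform. This
#' sensitivity-based pseudo-count encodes the prior belief that a
#' non-observed protein sits below the detection limit, while guaranteeing
#' a lower bound of a fourfold change against any observed value: for a
#' protein observed at intensity m in one group and missing in the other,
#' m / epsilon >= m / (min/4) >= 4 whenever m >= the global minimum.
#' Observed cells are never altered.
#'
#' @param table a (typically filtered) \code{ProteinQuantTable}.
#' @return list with \code{intensities} (complete raw-scale matrix),
#'   \code{epsilon} (the value used), \code{annotations}, and the table's
#'   \code{filter_counts} if present.
#' @export
impute_global_epsilon <- function(table) {
  stopifnot(inherits(table, "ProteinQuantTable"))
  x <- table$intensities
  if (all(is.na(x))) stop("cannot impute an all-missing table: epsilon is undefined")
  epsilon <- min(x, na.rm = TRUE) / 4
  x[is.na(x)] <- epsilon
  list(
    intensities = x,
    epsilon = epsilon,
    annotations = table$annotations,
    filter_counts = table$filter_counts
  )
}

#' Mean log-shift normalization of a log-intensity matrix
#'
#' Shifts each run (column) by a constant so that every per-run mean log
#' expression equals the grand mean of the input matrix. Protein-wise
#' differences within a run are preserved exactly, and applying the
#' normalization twice changes nothing.
#'
#' @param logmat numeric matrix of log intensities, proteins x runs, no
#'   missing values.
#' @return the normalized matrix.
#' @export
normalize_mean_logshift <- function(logmat) {
  stopifnot(is.matrix(logmat), !anyNA(logmat))
  run_means <- colMeans(logmat)
  sweep(logmat, 2, run_means - mean(logmat), "-")
}

#' Log-transform and normalize a complete raw intensity matrix
#'
#' Natural-log transforms a complete (imputed) raw intensity matrix and
#' applies \code{\link{normalize_mean_logshift}}, standardizing mean
#' expression levels per sample.
#'
#' @param intensities complete raw-scale matrix (all entries > 0), e.g.
#'   the \code{intensities} element of \code{\link{impute_global_epsilon}}.
#' @return natural-log, mean-shift-normalized matrix.
#' @export
log_and_normalize <- function(intensities) {
  intensities <- as.matrix(intensities)
  if (anyNA(intensities) || any(intensities <= 0)) {
    stop("log_and_normalize requires a complete matrix of positive intensities")
  }
  normalize_mean_logshift(log(intensities))
}

#' Full preprocessing: filter, impute, log, normalize
#'
#' Applies the four preprocessing stages in order — decoy/contaminant and
#' minimum-identification filtering, global-epsilon imputation on the raw
#' scale, natural-log transform, mean log-shift normalization — and
#' returns the modelling matrix together with the stage bookkeeping.
#'
#' @param table a \code{\link{protein_quant_table}}.
#' @param min_identifications passed to \code{\link{filter_proteins}}.
#' @return object of class \code{PreprocessedMatrix}: list with \code{E}
#'   (complete natural-log expression matrix, proteins x runs),
#'   \code{annotations}, \code{epsilon}, and per-filter removal counts
#'   \code{n_filtered_reverse}, \code{n_filtered_contaminant},
#'   \code{n_filtered_min_ident}.
#' @export
preprocess <- function(table, min_identifications = 3) {
  filtered <- filter_proteins(table, min_identifications)
  imputed <- impute_global_epsilon(filtered)
  structure(
    list(
      E = log_and_normalize(imputed$intensities),
      annotations = imputed$annotations,
      epsilon = imputed$epsilon,
      n_filtered_reverse = filtered$filter_counts$reverse,
      n_filtered_contaminant = filtered$filter_counts$contaminant,
      n_filtered_min_ident = filtered$filter_counts$min_ident
    ),
    class = "PreprocessedMatrix"
  )
}

#' @export
print.PreprocessedMatrix <- function(x, ...) {
  cat(sprintf(
    "PreprocessedMatrix: %d proteins x %d runs (epsilon = %.4g; removed %d reverse, %d contaminant, %d sparse)\n",
    nrow(x$E), ncol(x$E), x$epsilon,
    x$n_filtered_reverse, x$n_filtered_contaminant, x$n_filtered_min_ident
  ))
  invisible(x)
}
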