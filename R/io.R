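#' Protein quantification table
#'
#' Container for a MaxQuant proteinGroups-style quantification matrix: one
#' row per protein group, one intensity column per annotated run, plus
#' decoy (reversed-sequence) and contaminant flags. Intensities are raw
#' (not log) and nonnegative; missing quantifications are \code{NA}. A
#' reported intensity of exactly zero denotes non-quantification in
#' MaxQuant output and is converted to \code{NA} on construction.
#'
#' @param protein_id character vector of accessions, one per row.
#' @param intensities numeric matrix, proteins x runs; \code{NA} or 0 marks
#'   a missing quantification.
#' @param annotations sample annotation data.frame
#'   (\code{\link{sample_annotations}}), one row per intensity column, in
#'   column order.
#' @param is_reverse,is_contaminant logical flags per row (default all
#'   \code{FALSE}).
#' @return object of class \code{ProteinQuantTable}.
#' @export
protein_quant_table <- function(protein_id, intensities, annotations,
                                is_reverse = rep(FALSE, length(protein_id)),
                                is_contaminant = rep(FALSE, length(protein_id))) {
  annotations <- validate_annotations(annotations)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(protein_id)) {
    stop("intensity row count does not match number of protein ids")
  }
  if (ncol(intensities) != nrow(annotations)) {
    stop("intensity column count does not match number of annotated runs")
  }
  if (length(is_reverse) != length(protein_id) ||
      length(is_contaminant) != length(protein_id)) {
    stop("flag length does not match number of protein ids")
  }
  if (any(intensities < 0, na.rm = TRUE)) stop("negative intensity encountered")
  intensities[!is.na(intensities) & intensities == 0] <- NA_real_
  dimnames(intensities) <- list(protein_id, annotations$sample_id)
  structure(
    list(
      protein_id = as.character(protein_id),
      is_reverse = as.logical(is_reverse),
      is_contaminant = as.logical(is_contaminant),
      intensities = intensities,
      annotations = annotations
    ),
    class = "ProteinQuantTable"
  )
}

#' @export
print.ProteinQuantTable <- function(x, ...) {
  cat(sprintf(
    "ProteinQuantTable: %d proteins x %d runs (%d reverse, %d contaminant, %.1f%% missing)\n",
    nrow(x$intensities), ncol(x$intensities),
    sum(x$is_reverse), sum(x$is_contaminant),
    100 * mean(is.na(x$intensities))
  ))
  invisible(x)
}

#' Read a proteinGroups-style TSV
#'
#' Parses the MaxQuant proteinGroups dialect: a "Protein IDs" column, one
#' "LFQ intensity <label>" column per annotated run, and optional
#' "Reverse" / "Potential contaminant" columns in which "+" marks a flagged
#' row. Intensity cells of 0 or empty become missing. Columns are matched
#' to annotations by exact label after stripping the "LFQ intensity "
#' prefix; annotation order is preserved.
#'
#' @param path TSV file path.
#' @param annotations sample annotation data.frame; each
#'   \code{sample_id} must have a matching LFQ intensity column.
#' @return a \code{\link{protein_quant_table}}.
#' @export
read_protein_groups <- function(path, annotations) {
  annotations <- validate_annotations(annotations)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  if (!"Protein IDs" %in% names(raw)) {
    stop("input is missing required column 'Protein IDs'")
  }
  wanted <- paste0("LFQ intensity ", annotations$sample_id)
  absent <- setdiff(wanted, names(raw))
  if (length(absent) > 0) {
    stop("no intensity column for annotated run(s): ",
         paste(sub("^LFQ intensity ", "", absent), collapse = ", "))
  }
  intensities <- as.matrix(raw[, wanted, drop = FALSE])
  storage.mode(intensities) <- "double"
  parse_flag <- function(column) {
    if (!column %in% names(raw)) return(rep(FALSE, nrow(raw)))
    !is.na(raw[[column]]) & trimws(raw[[column]]) == "+"
  }
  protein_quant_table(
    protein_id = as.character(raw[["Protein IDs"]]),
    intensities = intensities,
    annotations = annotations,
    is_reverse = parse_flag("Reverse"),
    is_contaminant = parse_flag("Potential contaminant")
  )
}

#' Write a ProteinQuantTable as a proteinGroups-style TSV
#'
#' Inverse of \code{\link{read_protein_groups}}: missing cells are written
#' as 0 (the MaxQuant convention) and flags as "+" or empty.
#'
#' @param table a \code{ProteinQuantTable}.
#' @param path destination file path.
#' @export
write_protein_groups <- function(table, path) {
  stopifnot(inherits(table, "ProteinQuantTable"))
  intensities <- table$intensities
  intensities[is.na(intensities)] <- 0
  out <- data.frame(
    `Protein IDs` = table$protein_id,
    Reverse = ifelse(table$is_reverse, "+", ""),
    `Potential contaminant` = ifelse(table$is_contaminant, "+", ""),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  colnames(intensities) <- paste0("LFQ intensity ", table$annotations$sample_id)
  out <- cbind(out, as.data.frame(intensities, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a differential-abundance results table
#'
#' One row per (protein, contrast) with the reported log-fold change,
#' moderated t statistic, two-sided p-value, Benjamini-Yekutieli q-value
#' and the significance call (q < alpha, strict). Tab-separated, UTF-8,
#' "." decimal; numbers carry R's default 15 significant digits, so a
#' round trip is exact to that precision. Column order is fixed:
#' protein_id, contrast, logFC, t, p_value, q_value, significant.
#'
#' @param results a moderated, FDR-adjusted \code{ContrastResults} object
#'   (see \code{\link{empirical_bayes_moderate}} and
#'   \code{\link{adjust_results_fdr}}), or a data.frame already in the
#'   output layout.
#' @param path destination / source file path.
#' @param logfc_base base in which the logFC column is reported (default
#'   2); the model estimates are natural-log internally.
#' @export
write_results <- function(results, path, logfc_base = 2) {
  tab <- if (is.data.frame(results)) results else
    results_table(results, logfc_base = logfc_base)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(protein_id = "character", contrast = "character"))
}
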