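#' Render a sample label in the A/F c/i bio.tech scheme
#'
#' Builds the compact run labels used throughout the pipeline outputs:
#' age is abbreviated "A" (adult) or "F" (fetal), condition "c" (control)
#' or "i" (injured), followed by biological and technical replicate numbers
#' separated by a dot. Example: adult, control, biological replicate 1,
#' technical replicate 2 renders as "Ac1.2".
#'
#' @param age character vector, each "adult" or "fetal".
#' @param condition character vector, each "control" or "injured".
#' @param bio_rep positive integer vector, biological replicate index.
#' @param tech_rep positive integer vector, technical replicate index.
#' @return character vector of labels.
#' @export
format_sample_label <- function(age, condition, bio_rep, tech_rep) {
  age <- match_levels(age, c("adult", "fetal"), "age")
  condition <- match_levels(condition, c("control", "injured"), "condition")
  stopifnot(bio_rep >= 1, tech_rep >= 1)
  paste0(
    ifelse(age == "adult", "A", "F"),
    ifelse(condition == "control", "c", "i"),
    as.integer(bio_rep), ".", as.integer(tech_rep)
  )
}

match_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- !x %in% levels
  if (any(bad)) {
    stop(sprintf(
      "invalid %s value(s): %s (expected one of: %s)",
      what, paste(unique(x[bad]), collapse = ", "),
      paste(levels, collapse = ", ")
    ))
  }
  x
}

#' Sample annotations for the 2 x 2 nested replicate design
#'
#' Enumerates every (age, condition, biological replicate, technical
#' replicate) combination exactly once, in the canonical display order:
#' adult before fetal, control before injured, then bio.tech. With the
#' defaults this yields the 24-run design (2 ages x 2 conditions x 3
#' biological x 2 technical replicates).
#'
#' @param n_bio biological replicates per group (default 3).
#' @param n_tech technical replicates per biological replicate (default 2).
#' @return data.frame with columns \code{sample_id}, \code{age},
#'   \code{condition}, \code{bio_rep}, \code{tech_rep}; one row per run.
#' @export
sample_annotations <- function(n_bio = 3, n_tech = 2) {
  stopifnot(n_bio >= 1, n_tech >= 1)
  ann <- expand.grid(
    tech_rep = seq_len(n_tech),
    bio_rep = seq_len(n_bio),
    condition = c("control", "injured"),
    age = c("adult", "fetal"),
    stringsAsFactors = FALSE
  )[, c("age", "condition", "bio_rep", "tech_rep")]
  ann <- data.frame(
    sample_id = format_sample_label(ann$age, ann$condition, ann$bio_rep, ann$tech_rep),
    ann, stringsAsFactors = FALSE
  )
  rownames(ann) <- NULL
  validate_annotations(ann)
}

validate_annotations <- function(ann) {
  required <- c("sample_id", "age", "condition", "bio_rep", "tech_rep")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  ann$age <- match_levels(ann$age, c("adult", "fetal"), "age")
  ann$condition <- match_levels(ann$condition, c("control", "injured"), "condition")
  key <- paste(ann$age, ann$condition, ann$bio_rep, ann$tech_rep)
  if (anyDuplicated(key)) {
    stop("duplicated (age, condition, bio_rep, tech_rep) combination in annotations")
  }
  if (anyDuplicated(ann$sample_id)) stop("duplicated sample_id in annotations")
  ann
}

#' Design specification: group factor and replicate blocks
#'
#' Derives from the sample annotations the two structures the per-protein
#' linear models need: a four-level group factor (age x condition cell
#' means) and a block identifier grouping the technical replicates of each
#' biological replicate. Every run belongs to exactly one group and one
#' block; the within-block correlation of technical replicates is the
#' nuisance parameter estimated by
#' \code{\link{estimate_consensus_correlation}}.
#'
#' @param annotations annotation data.frame as from
#'   \code{\link{sample_annotations}}.
#' @return object of class \code{DesignSpec}: list with \code{group}
#'   (factor, levels adult.control, adult.injured, fetal.control,
#'   fetal.injured), \code{block} (factor, one level per biological
#'   replicate), and \code{annotations}.
#' @export
design_spec <- function(annotations) {
  ann <- validate_annotations(annotations)
  group <- factor(
    paste(ann$age, ann$condition, sep = "."),
    levels = c("adult.control", "adult.injured", "fetal.control", "fetal.injured")
  )
  block <- factor(paste(ann$age, ann$condition, ann$bio_rep, sep = "."))
  structure(
    list(group = group, block = block, annotations = ann),
    class = "DesignSpec"
  )
}
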