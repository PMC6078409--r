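venn_letters <- c("T", "F", "A", "D")

#' Canonical region keys of the four-set Venn partition
#'
#' The 15 nonempty subsets of {T, F, A, D} (T = total response, F = fetal
#' response, A = adult response, D = response difference), each rendered
#' as its letters in the fixed order T, F, A, D and listed by increasing
#' subset size, so reports are deterministic: "T", "F", "A", "D", "TF",
#' "TA", "TD", "FA", "FD", "AD", "TFA", "TFD", "TAD", "FAD", "TFAD".
#'
#' @return character vector of the 15 region keys.
#' @export
venn_region_keys <- function() {
  subsets <- unlist(lapply(1:4, function(k) {
    apply(utils::combn(venn_letters, k), 2, paste, collapse = "")
  }))
  subsets
}

#' Partition four significance sets into the 15 Venn regions
#'
#' Assigns every protein in the union of the four sets to exactly one
#' region by its exact membership signature. Conservation holds by
#' construction: for each test X, the counts of all regions containing X
#' sum to |set X|, and all region counts sum to the size of the union.
#'
#' @param total,fetal,adult,difference character vectors of protein ids
#'   significant in the total-response, fetal-response, adult-response and
#'   response-difference tests (empty sets allowed).
#' @return object of class \code{VennPartition}: list with \code{counts}
#'   (named integer vector over \code{\link{venn_region_keys}}) and
#'   \code{members} (named list of id vectors per region).
#' @export
venn_partition <- function(total, fetal, adult, difference) {
  sets <- list(T = unique(as.character(total)),
               F = unique(as.character(fetal)),
               A = unique(as.character(adult)),
               D = unique(as.character(difference)))
  ids <- unique(unlist(sets, use.names = FALSE))
  keys <- venn_region_keys()
  members <- stats::setNames(vector("list", length(keys)), keys)
  members[] <- list(character(0))
  if (length(ids) > 0) {
    sig <- vapply(ids, function(id) {
      paste(venn_letters[vapply(sets, function(s) id %in% s, logical(1))],
            collapse = "")
    }, character(1))
    for (key in unique(sig)) members[[key]] <- unname(ids[sig == key])
  }
  counts <- vapply(members, length, integer(1))
  structure(list(counts = counts, members = members), class = "VennPartition")
}

#' Build a VennPartition from known region counts
#'
#' For reproducing published region configurations where only the counts
#' (not the protein identities) are available. Counts must be nonnegative;
#' absent regions default to zero.
#'
#' @param counts named numeric vector; names must be canonical region keys.
#' @return a \code{VennPartition} with \code{members = NULL}.
#' @export
venn_partition_from_counts <- function(counts) {
  keys <- venn_region_keys()
  bad <- setdiff(names(counts), keys)
  if (length(bad) > 0) {
    stop("unknown region key(s): ", paste(bad, collapse = ", "),
         " (letters must appear in T, F, A, D order)")
  }
  if (any(counts < 0)) stop("region counts must be nonnegative")
  full <- stats::setNames(integer(length(keys)), keys)
  full[names(counts)] <- as.integer(counts)
  structure(list(counts = full, members = NULL), class = "VennPartition")
}

#' Summarize a Venn partition into the published headline counts
#'
#' For each of the four tests, the implicated total is the sum of counts
#' over all regions containing the test's letter. For the fetal, adult and
#' difference tests, the "newly identified" count additionally excludes
#' every region containing T (the total response); for T itself, newly
#' identified is not defined and reported as \code{NA}. The
#' difference-test breakdown lists the eight regions containing D, keyed
#' by the tests that had already implicated the protein.
#'
#' @param partition a \code{VennPartition}.
#' @return list with \code{implicated} (named vector over T, F, A, D),
#'   \code{newly_identified} (named vector; NA for T) and
#'   \code{difference_breakdown} (named vector over the eight D regions).
#' @export
summarize_partition <- function(partition) {
  stopifnot(inherits(partition, "VennPartition"))
  counts <- partition$counts
  keys <- names(counts)
  has <- function(letter) grepl(letter, keys, fixed = TRUE)

  implicated <- vapply(venn_letters, function(l) sum(counts[has(l)]), numeric(1))
  newly <- vapply(venn_letters, function(l) {
    if (l == "T") return(NA_real_)
    sum(counts[has(l) & !has("T")])
  }, numeric(1))

  d_keys <- keys[has("D")]
  prior <- vapply(d_keys, function(k) {
    others <- setdiff(strsplit(k, "")[[1]], "D")
    if (length(others) == 0) "none" else
      paste(c(T = "total", F = "fetal", A = "adult")[others], collapse = "+")
  }, character(1))
  breakdown <- stats::setNames(as.numeric(counts[d_keys]), prior)

  list(
    implicated = implicated,
    newly_identified = newly,
    difference_breakdown = breakdown
  )
}

#' @export
print.VennPartition <- function(x, ...) {
  cat("VennPartition (15 regions):\n")
  print(x$counts)
  invisible(x)
}

#' Write a Venn partition as a two-column TSV
#'
#' @param partition a \code{VennPartition}.
#' @param path destination file path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "VennPartition"))
  utils::write.table(
    data.frame(region = names(partition$counts),
               count = as.integer(partition$counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
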