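#' Pairwise Spearman correlation of runs
#'
#' Spearman rank correlation (midranks for ties) between every pair of
#' runs, computed over all proteins of the expression matrix. Because
#' ranks are invariant to strictly monotone maps, the result does not
#' depend on the log transform or the mean log-shift normalization, and
#' for runs without imputed cells it is also unaffected by the global
#' epsilon imputation.
#'
#' @param matrix a \code{PreprocessedMatrix} or numeric matrix (proteins x
#'   runs), at least 2 proteins. May contain \code{NA} when
#'   \code{use = "pairwise"}.
#' @param use observations to use, as in \code{stats::cor}: "everything"
#'   (default; computes on the complete, imputed matrix) or "pairwise"
#'   (documented option for raw observed-only data).
#' @return symmetric correlation matrix with run labels as dimnames; unit
#'   diagonal; a constant run yields \code{NA} entries with a warning.
#' @export
spearman_matrix <- function(matrix, use = c("everything", "pairwise")) {
  use <- match.arg(use)
  E <- expr_matrix(matrix)
  if (nrow(E) < 2) stop("need at least 2 proteins for sample correlations")
  constant <- apply(E, 2, function(col) {
    obs <- col[!is.na(col)]
    length(obs) > 0 && all(obs == obs[1])
  })
  if (any(constant)) {
    warning("constant run(s) with undefined correlation: ",
            paste(colnames(E)[constant], collapse = ", "))
  }
  R <- suppressWarnings(
    stats::cor(E, method = "spearman",
               use = if (use == "everything") "everything" else
                 "pairwise.complete.obs")
  )
  dg <- diag(R)
  dg[!constant] <- 1
  diag(R) <- dg
  R
}

#' Correlation-ellipse glyph coordinates
#'
#' Parametric glyph visualizing a correlation coefficient rho as an
#' ellipse: points (x, y) = (cos(theta + d/2), cos(theta - d/2)) for
#' equally spaced theta in [0, 2 pi), where d = arccos(rho). At rho = 1
#' the glyph collapses to the line y = x, at rho = -1 to y = -x, and at
#' rho = 0 (d = pi/2) the points lie on the unit circle; the closer |rho|
#' is to 1, the narrower the ellipse.
#'
#' @param rho correlation in [-1, 1].
#' @param n_points number of sampled angles (>= 3; default 64).
#' @return object of class \code{EllipseGlyph}: list with \code{rho},
#'   \code{d} and \code{points} (data.frame theta, x, y).
#' @export
ellipse_coordinates <- function(rho, n_points = 64) {
  stopifnot(is.numeric(rho), length(rho) == 1)
  if (!is.finite(rho) || abs(rho) > 1) stop("rho must lie in [-1, 1]")
  if (n_points < 3) stop("n_points must be >= 3")
  d <- acos(rho)
  theta <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  structure(
    list(
      rho = rho, d = d,
      points = data.frame(theta = theta,
                          x = cos(theta + d / 2),
                          y = cos(theta - d / 2))
    ),
    class = "EllipseGlyph"
  )
}

#' Write a correlation matrix / glyph coordinates as TSV
#'
#' @param R symmetric correlation matrix (run labels as dimnames).
#' @param path destination file path.
#' @export
write_correlation_matrix <- function(R, path) {
  out <- data.frame(sample_id = rownames(R), R, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correlation_matrix
#' @param glyph an \code{EllipseGlyph}.
#' @export
write_glyph <- function(glyph, path) {
  stopifnot(inherits(glyph, "EllipseGlyph"))
  utils::write.table(glyph$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
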