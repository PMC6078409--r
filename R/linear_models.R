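#' The five study contrasts over the four group means
#'
#' Rows are named contrasts, columns the four group means in the fixed
#' order (adult.control, adult.injured, fetal.control, fetal.injured):
#' \describe{
#'   \item{adult_response}{AdultInjured - AdultControl}
#'   \item{fetal_response}{FetalInjured - FetalControl}
#'   \item{total_response}{(adult_response + fetal_response) / 2}
#'   \item{response_difference}{fetal_response - adult_response, the
#'     second-level contrast testing whether the injury response differs
#'     by age}
#'   \item{baseline_difference}{FetalControl - AdultControl}
#' }
#' By construction the response_difference row equals the fetal_response
#' row minus the adult_response row, and total_response equals their mean.
#'
#' @return 5 x 4 numeric contrast matrix.
#' @export
default_contrasts <- function() {
  groups <- c("adult.control", "adult.injured", "fetal.control", "fetal.injured")
  C <- rbind(
    adult_response      = c(-1,  1,  0, 0),
    fetal_response      = c( 0,  0, -1, 1),
    total_response      = c(-0.5, 0.5, -0.5, 0.5),
    response_difference = c( 1, -1, -1, 1),
    baseline_difference = c(-1,  0,  1, 0)
  )
  colnames(C) <- groups
  C
}

expr_matrix <- function(x) {
  if (inherits(x, "PreprocessedMatrix")) x$E else as.matrix(x)
}

#' Estimate the consensus within-block correlation
#'
#' Technical replicates of one biological replicate share the biological
#' replicate's deviation, making them correlated; a single consensus value
#' of that correlation is estimated across all proteins and used as the
#' working correlation of the generalized least squares fit.
#'
#' Per protein, residuals after removing group means are paired within
#' each block (both orientations, so the estimate is symmetric) and their
#' Pearson correlation computed; per-protein estimates are pooled by a 10%
#' trimmed mean on the Fisher z scale and back-transformed. Because
#' removing the group mean from a group of \code{n_g} runs induces a
#' negative correlation among its residuals, the pooled raw correlation r
#' understates the true within-block correlation rho; under compound
#' symmetry they relate by r = (rho - c) / (1 - c) with
#' c = (1 + (n_tech - 1) rho) / n_g, which is inverted in closed form:
#' rho = (r (n_g - 1) + 1) / (n_g + (n_tech - 1)(r - 1)).
#' The result is clamped to [-0.95, 0.99].
#'
#' @param matrix a \code{PreprocessedMatrix} or complete numeric matrix
#'   (proteins x runs); at least 10 proteins.
#' @param design a \code{\link{design_spec}}; every block must contain at
#'   least two runs.
#' @return object of class \code{ConsensusCorrelation}: list with
#'   \code{rho} (the corrected consensus estimate), \code{rho_raw} (the
#'   pooled residual correlation before bias correction) and
#'   \code{n_proteins}.
#' @export
estimate_consensus_correlation <- function(matrix, design) {
  E <- expr_matrix(matrix)
  stopifnot(inherits(design, "DesignSpec"), ncol(E) == length(design$group))
  if (nrow(E) < 10) stop("need at least 10 proteins to estimate a consensus correlation")
  block_sizes <- table(design$block)
  if (all(block_sizes < 2)) {
    stop("all blocks have a single run: within-block correlation is unidentifiable")
  }

  # residuals after removing group means
  group_mean <- t(apply(E, 1, function(y) tapply(y, design$group, mean)))
  resid <- E - group_mean[, as.character(design$group), drop = FALSE]

  # all within-block run pairs, both orientations
  idx <- do.call(rbind, lapply(split(seq_along(design$block), design$block), function(runs) {
    if (length(runs) < 2) return(NULL)
    pairs <- t(utils::combn(runs, 2))
    rbind(pairs, pairs[, 2:1, drop = FALSE])
  }))

  r_protein <- vapply(seq_len(nrow(resid)), function(i) {
    x <- resid[i, idx[, 1]]
    y <- resid[i, idx[, 2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  r_protein <- r_protein[is.finite(r_protein)]
  if (length(r_protein) < 10) stop("too few proteins with estimable residual correlation")

  z <- atanh(pmin(pmax(r_protein, -1 + 1e-8), 1 - 1e-8))
  r_pool <- tanh(mean(z, trim = 0.1))

  n_g <- mean(table(design$group))
  k <- mean(block_sizes[block_sizes >= 2]) - 1
  rho <- (r_pool * (n_g - 1) + 1) / (n_g + k * (r_pool - 1))
  rho <- min(max(rho, -0.95), 0.99)

  structure(
    list(rho = rho, rho_raw = r_pool, n_proteins = length(r_protein)),
    class = "ConsensusCorrelation"
  )
}

#' @export
print.ConsensusCorrelation <- function(x, ...) {
  cat(sprintf("ConsensusCorrelation: rho_block = %.4f (raw pooled r = %.4f, %d proteins)\n",
              x$rho, x$rho_raw, x$n_proteins))
  invisible(x)
}

# Symmetric inverse square root of a compound-symmetry correlation matrix
# (1-rho) I + rho J on a block of size t, used to whiten each block.
cs_whitener <- function(t, rho) {
  a <- 1 / sqrt(1 - rho)
  b <- 1 / sqrt(1 + (t - 1) * rho)
  (a * (diag(t) - matrix(1 / t, t, t))) + b * matrix(1 / t, t, t)
}

#' Fit per-protein generalized least squares models with block correlation
#'
#' Fits, separately for each protein, the group-mean model by generalized
#' least squares with within-block covariance proportional to
#' (1 - rho) I + rho J on each block of technical replicates (J the
#' all-ones matrix), and evaluates the requested contrasts. With rho = 0
#' the fit is ordinary least squares exactly. Because the design and the
#' working correlation are shared, the whitening transform and the hat
#' matrix are computed once and applied to all proteins.
#'
#' @param matrix a \code{PreprocessedMatrix} or complete numeric
#'   log-expression matrix (proteins x runs).
#' @param design a \code{\link{design_spec}} covering all runs; every
#'   group must be non-empty.
#' @param contrasts contrast matrix (rows = contrasts, columns = the four
#'   groups); default \code{\link{default_contrasts}}.
#' @param rho consensus within-block correlation: a number in (-1, 1) or a
#'   \code{ConsensusCorrelation}.
#' @return object of class \code{ContrastResults}: list with
#'   \code{protein_id}, \code{coefficients} (proteins x contrasts contrast
#'   estimates, on the scale of the input matrix, i.e. natural log),
#'   \code{stdev_unscaled} (per-contrast unscaled standard errors,
#'   identical across proteins), \code{s2} (residual variances),
#'   \code{df_residual} (n_runs - 4), \code{contrasts} and \code{rho}.
#' @export
fit_protein_models <- function(matrix, design, contrasts = default_contrasts(),
                               rho = 0) {
  E <- expr_matrix(matrix)
  if (anyNA(E)) stop("expression matrix must be complete (impute first)")
  stopifnot(inherits(design, "DesignSpec"), ncol(E) == length(design$group))
  if (inherits(rho, "ConsensusCorrelation")) rho <- rho$rho
  stopifnot(is.numeric(rho), length(rho) == 1, rho > -1, rho < 1)

  empty <- levels(design$group)[tabulate(design$group, nbins = nlevels(design$group)) == 0]
  if (length(empty) > 0) {
    stop("design is singular: no runs in group(s) ", paste(empty, collapse = ", "))
  }
  contrasts <- as.matrix(contrasts)
  if (ncol(contrasts) != nlevels(design$group)) {
    stop("contrast matrix must have one column per group")
  }

  n <- ncol(E)
  X <- stats::model.matrix(~ 0 + design$group)
  colnames(X) <- levels(design$group)
  X <- X[, colnames(contrasts), drop = FALSE]

  W <- diag(n)
  for (runs in split(seq_len(n), design$block)) {
    W[runs, runs] <- cs_whitener(length(runs), rho)
  }
  Xw <- W %*% X
  Ew <- E %*% W  # W symmetric: whitened responses per protein (rows)

  XtXinv <- solve(crossprod(Xw))
  beta <- Ew %*% Xw %*% XtXinv                    # proteins x 4 group means
  fitted <- beta %*% t(Xw)
  df <- n - ncol(X)
  s2 <- rowSums((Ew - fitted)^2) / df

  est <- beta %*% t(contrasts)
  stdev_unscaled <- sqrt(diag(contrasts %*% XtXinv %*% t(contrasts)))
  names(stdev_unscaled) <- rownames(contrasts)

  structure(
    list(
      protein_id = rownames(E) %||% sprintf("row%d", seq_len(nrow(E))),
      coefficients = est,
      stdev_unscaled = stdev_unscaled,
      s2 = unname(s2),
      df_residual = df,
      contrasts = contrasts,
      rho = rho
    ),
    class = "ContrastResults"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Invert the trigamma function
#'
#' Solves trigamma(y) = x for y > 0 by Newton iteration; used to match the
#' variance of log residual variances to a scaled F distribution.
#'
#' @param x positive numeric vector.
#' @return y with \code{trigamma(y) = x}; \code{Inf} where x <= 0.
#' @export
trigamma_inverse <- function(x) {
  y <- rep(NA_real_, length(x))
  y[x <= 0] <- Inf
  todo <- which(is.finite(x) & x > 0)
  if (length(todo) == 0) return(y)
  xx <- x[todo]
  yy <- 0.5 + 1 / xx
  for (iter in 1:50) {
    tri <- trigamma(yy)
    dif <- tri * (1 - tri / xx) / psigamma(yy, deriv = 2)
    yy <- yy + dif
    if (max(abs(dif) / yy) < 1e-10) break
  }
  y[todo] <- yy
  y
}

#' Empirical-Bayes moderation of per-protein variances
#'
#' Shrinks each protein's residual variance toward a common prior
#' estimated from all proteins, stabilizing the t-tests at small sample
#' sizes. The marginal model s2 ~ s0^2 F(d, d0) is fitted by matching the
#' first two moments of log(s2): with e = log(s2) - digamma(d/2) +
#' log(d/2), the excess variance of e over trigamma(d/2) identifies d0 via
#' the trigamma inverse, and its mean identifies s0^2. The moderated
#' variance is the prior-weighted average
#' s2_post = (d0 s0^2 + d s2) / (d0 + d), the moderated t statistic is
#' estimate / (stdev_unscaled * sqrt(s2_post)), and two-sided p-values use
#' a t reference with d + d0 degrees of freedom. If the observed log
#' variances are no more dispersed than chi-square sampling alone allows,
#' d0 is infinite: every s2_post equals s0^2 and the reference is normal.
#'
#' @param results a \code{ContrastResults} from
#'   \code{\link{fit_protein_models}} (at least 10 proteins with positive
#'   residual degrees of freedom).
#' @return the results object extended with \code{df_prior} (d0),
#'   \code{s2_prior} (s0^2), \code{s2_post}, \code{t} and \code{p_value}
#'   (proteins x contrasts matrices).
#' @export
empirical_bayes_moderate <- function(results) {
  stopifnot(inherits(results, "ContrastResults"))
  d <- results$df_residual
  s2 <- results$s2
  if (sum(d > 0 & is.finite(s2)) < 10) {
    stop("need at least 10 proteins with positive residual df to moderate variances")
  }
  pos <- is.finite(s2) & s2 > 0
  if (!all(pos)) {
    warning(sum(!pos), " protein(s) with zero residual variance excluded from prior estimation")
  }
  e <- log(s2[pos]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }

  moderate_with_prior(results, df_prior = d0, s2_prior = s02)
}

#' @rdname empirical_bayes_moderate
#' @param df_prior prior degrees of freedom d0 (0, positive, or Inf).
#' @param s2_prior prior variance s0^2 (> 0).
#' @details \code{moderate_with_prior} applies the shrinkage and testing
#'   step for given hyperparameters; \code{empirical_bayes_moderate}
#'   estimates (d0, s0^2) from the data and then calls it. At d0 = 0 the
#'   moderated t reduces to the ordinary t with d degrees of freedom; at
#'   d0 = Inf every moderated variance equals s0^2 and the reference is
#'   normal.
#' @export
moderate_with_prior <- function(results, df_prior, s2_prior) {
  stopifnot(inherits(results, "ContrastResults"),
            df_prior >= 0, s2_prior > 0)
  d <- results$df_residual
  s2 <- results$s2
  s2_post <- if (is.infinite(df_prior)) rep(s2_prior, length(s2)) else
    (df_prior * s2_prior + d * s2) / (df_prior + d)
  se <- outer(sqrt(s2_post), results$stdev_unscaled)
  tstat <- results$coefficients / se
  df_total <- d + df_prior
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)

  results$df_prior <- df_prior
  results$s2_prior <- s2_prior
  results$s2_post <- s2_post
  results$df_total <- df_total
  results$t <- tstat
  results$p_value <- pval
  results
}

#' Benjamini-Yekutieli adjustment of p-values
#'
#' Step-up FDR adjustment valid under arbitrary dependence:
#' q_(i) = min over j >= i of min(1, p_(j) * m * c(m) / j) with the
#' harmonic inflation c(m) = sum_{k=1..m} 1/k; input order is restored on
#' return. Delegates to \code{stats::p.adjust(method = "BY")}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
adjust_benjamini_yekutieli <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BY")
}

#' Add per-contrast Benjamini-Yekutieli q-values
#'
#' Each contrast is treated as its own test family: q-values are computed
#' by \code{\link{adjust_benjamini_yekutieli}} within each column of the
#' p-value matrix separately.
#'
#' @param results moderated \code{ContrastResults}.
#' @return the results object with a \code{q_value} matrix added.
#' @export
adjust_results_fdr <- function(results) {
  stopifnot(inherits(results, "ContrastResults"))
  if (is.null(results$p_value)) stop("moderate the results before FDR adjustment")
  results$q_value <- apply(results$p_value, 2, adjust_benjamini_yekutieli)
  dimnames(results$q_value) <- dimnames(results$p_value)
  results
}

#' Call significant proteins per contrast
#'
#' A protein is significant for a contrast when its Benjamini-Yekutieli
#' q-value is strictly below \code{alpha} (q = alpha exactly is not
#' called).
#'
#' @param results FDR-adjusted \code{ContrastResults}.
#' @param alpha significance threshold on the q-value (default 0.05).
#' @return named list of character vectors of protein ids, one per
#'   contrast.
#' @export
call_significant <- function(results, alpha = 0.05) {
  stopifnot(inherits(results, "ContrastResults"))
  if (is.null(results$q_value)) stop("adjust the results before calling significance")
  stopifnot(alpha > 0, alpha < 1)
  out <- lapply(seq_len(ncol(results$q_value)), function(j) {
    results$protein_id[results$q_value[, j] < alpha]
  })
  names(out) <- colnames(results$q_value)
  out
}

#' Flatten contrast results into a long table
#'
#' One row per (protein, contrast) with the log-fold change converted to
#' the requested base (estimates are natural-log internally), moderated t,
#' p-value, q-value and the significance flag.
#'
#' @param results FDR-adjusted \code{ContrastResults}.
#' @param logfc_base base for the reported logFC column (default 2).
#' @param alpha threshold for the significance flag (default 0.05).
#' @return data.frame with columns protein_id, contrast, logFC, t,
#'   p_value, q_value, significant.
#' @export
results_table <- function(results, logfc_base = 2, alpha = 0.05) {
  stopifnot(inherits(results, "ContrastResults"))
  if (is.null(results$q_value)) stop("moderate and adjust the results first")
  contrasts <- colnames(results$coefficients)
  out <- do.call(rbind, lapply(contrasts, function(ct) {
    data.frame(
      protein_id = results$protein_id,
      contrast = ct,
      logFC = results$coefficients[, ct] / log(logfc_base),
      t = results$t[, ct],
      p_value = results$p_value[, ct],
      q_value = results$q_value[, ct],
      significant = results$q_value[, ct] < alpha,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.ContrastResults <- function(x, ...) {
  cat(sprintf("ContrastResults: %d proteins x %d contrasts (rho = %.3f, df = %d%s)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$rho, x$df_residual,
              if (!is.null(x$df_prior)) sprintf(", d0 = %.2f", x$df_prior) else ""))
  invisible(x)
}
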