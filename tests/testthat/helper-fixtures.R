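# Small in-code fixtures shared across test files.

# A tiny fully annotated table: n_proteins x the standard 24-run design,
# deterministic values unless intensities are supplied.
toy_table <- function(n_proteins = 3, intensities = NULL,
                      is_reverse = rep(FALSE, n_proteins),
                      is_contaminant = rep(FALSE, n_proteins),
                      n_bio = 3, n_tech = 2) {
  ann <- sample_annotations(n_bio, n_tech)
  if (is.null(intensities)) {
    intensities <- matrix(
      100 * seq_len(n_proteins * nrow(ann)),
      nrow = n_proteins
    )
  }
  protein_quant_table(sprintf("P%03d", seq_len(n_proteins)), intensities, ann,
                      is_reverse = is_reverse, is_contaminant = is_contaminant)
}

# A matrix whose 24 runs carry the given four group means exactly
# (adult.control, adult.injured, fetal.control, fetal.injured), plus
# optional iid noise.
group_mean_matrix <- function(means, n_proteins = 1, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  des <- design_spec(sample_annotations())
  base <- matrix(rep(means[as.integer(des$group)], each = n_proteins),
                 nrow = n_proteins)
  if (noise_sd > 0) base <- base + matrix(rnorm(length(base), 0, noise_sd),
                                          nrow = n_proteins)
  rownames(base) <- sprintf("P%03d", seq_len(n_proteins))
  colnames(base) <- des$annotations$sample_id
  base
}

# Independent dense-matrix GLS oracle: explicit covariance inversion.
brute_force_gls <- function(y, design, contrasts, rho) {
  n <- length(y)
  R <- diag(n)
  for (runs in split(seq_len(n), design$block)) {
    R[runs, runs] <- (1 - rho) * diag(length(runs)) +
      rho * matrix(1, length(runs), length(runs))
  }
  X <- stats::model.matrix(~ 0 + design$group)
  colnames(X) <- levels(design$group)
  Rinv <- solve(R)
  XtRX <- t(X) %*% Rinv %*% X
  beta <- solve(XtRX, t(X) %*% Rinv %*% y)
  resid <- y - X %*% beta
  df <- n - ncol(X)
  s2 <- as.numeric(t(resid) %*% Rinv %*% resid) / df
  est <- contrasts %*% beta
  se_unscaled <- sqrt(diag(contrasts %*% solve(XtRX) %*% t(contrasts)))
  list(est = as.numeric(est), se_unscaled = se_unscaled, s2 = s2, df = df)
}

# Minimal ContrastResults with given residual variances, for testing the
# empirical-Bayes moderation in isolation.
synthetic_fit <- function(s2, df, coefficients = NULL) {
  n <- length(s2)
  if (is.null(coefficients)) {
    coefficients <- matrix(0, n, 1, dimnames = list(NULL, "adult_response"))
  }
  structure(
    list(
      protein_id = sprintf("P%05d", seq_len(n)),
      coefficients = coefficients,
      stdev_unscaled = stats::setNames(rep(sqrt(2 / 6), ncol(coefficients)),
                                       colnames(coefficients)),
      s2 = s2,
      df_residual = df,
      contrasts = NULL,
      rho = 0
    ),
    class = "ContrastResults"
  )
}

# The Fig.-style published 15-region configuration used by the
# decomposition tests (counts as printed in the source legend).
published_region_counts <- function() {
  c(T = 7, F = 3, A = 64, D = 3,
    TF = 9, TA = 56, TD = 0, FA = 0, FD = 8, AD = 45,
    TFA = 15, TFD = 35, TAD = 261, FAD = 2, TFAD = 2)
}

# Direct step-up evaluation of the Benjamini-Yekutieli formula, kept
# independent of stats::p.adjust.
by_stepup_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m * cm / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
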