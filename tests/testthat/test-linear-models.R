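test_that("contrast matrix satisfies its defining identities", {
  C <- default_contrasts()
  expect_identical(unname(C["response_difference", ]),
                   unname(C["fetal_response", ] - C["adult_response", ]))
  expect_identical(unname(C["total_response", ]),
                   unname((C["fetal_response", ] + C["adult_response", ]) / 2))
})

test_that("contrast estimates are the expected arithmetic on group means", {
  # group means (Ac, Ai, Fc, Fi) = (1, 2, 3, 5)
  E <- group_mean_matrix(c(1, 2, 3, 5))
  des <- design_spec(sample_annotations())
  fit <- fit_protein_models(E, des, rho = 0)
  est <- fit$coefficients[1, ]
  expect_equal(unname(est["adult_response"]), 1)
  expect_equal(unname(est["fetal_response"]), 2)
  expect_equal(unname(est["total_response"]), 1.5)
  expect_equal(unname(est["response_difference"]), 1)
  expect_equal(unname(est["baseline_difference"]), 2)
  # perfect fit: s2 = 0, df = n_runs - 4
  expect_equal(fit$s2, 0)
  expect_equal(fit$df_residual, 20)
})

test_that("GLS with rho = 0 equals ordinary least squares exactly", {
  set.seed(21)
  E <- group_mean_matrix(c(0, 1, -1, 2), n_proteins = 30, noise_sd = 1)
  des <- design_spec(sample_annotations())
  fit <- fit_protein_models(E, des, rho = 0)
  C <- default_contrasts()
  X <- model.matrix(~ 0 + des$group)
  for (i in c(1, 17)) {
    ols <- lm.fit(X, E[i, ])
    expect_equal(unname(fit$coefficients[i, ]),
                 unname(as.numeric(C %*% ols$coefficients)),
                 tolerance = 1e-12)
    expect_equal(fit$s2[i], sum(ols$residuals^2) / 20, tolerance = 1e-12)
  }
})

test_that("GLS matches a dense-covariance brute-force oracle", {
  set.seed(33)
  des <- design_spec(sample_annotations())
  C <- default_contrasts()
  for (rho in c(0.4, -0.3, 0.9)) {
    E <- group_mean_matrix(c(0, 1, -1, 2), n_proteins = 5, noise_sd = 1,
                           seed = 100 + round(10 * rho))
    fit <- fit_protein_models(E, des, rho = rho)
    for (i in seq_len(5)) {
      oracle <- brute_force_gls(E[i, ], des, C, rho)
      expect_equal(unname(fit$coefficients[i, ]), oracle$est, tolerance = 1e-8)
      expect_equal(fit$s2[i], oracle$s2, tolerance = 1e-8)
    }
    expect_equal(unname(fit$stdev_unscaled),
                 unname(brute_force_gls(E[1, ], des, C, rho)$se_unscaled),
                 tolerance = 1e-8)
  }
})

test_that("singular designs are rejected naming the empty group", {
  ann <- sample_annotations()
  keep <- ann$age == "adult" | ann$condition == "control"
  des_ok <- design_spec(ann)
  E <- group_mean_matrix(c(1, 2, 3, 4))
  sub <- list(group = factor(des_ok$group[keep],
                             levels = levels(des_ok$group)),
              block = droplevels(des_ok$block[keep]),
              annotations = ann[keep, ])
  class(sub) <- "DesignSpec"
  expect_error(fit_protein_models(E[, keep, drop = FALSE], sub),
               "fetal.injured")
})

test_that("consensus correlation recovers the generator truth", {
  sim <- simulate_dataset(sim_config(n_proteins = 2000, tau = 0.5, sigma = 0.5,
                                     missing_midpoint = -50, n_reverse = 0,
                                     n_contaminant = 0, seed = 14))
  des <- design_spec(sim$table$annotations)
  est <- estimate_consensus_correlation(log(sim$table$intensities), des)
  expect_lt(abs(est$rho - 0.5), 0.1)
})

test_that("consensus correlation handles the degenerate extremes", {
  des <- design_spec(sample_annotations())
  set.seed(6)
  # duplicated technical replicates: zero tech noise -> upper clamp
  blocks <- split(seq_len(24), des$block)
  E <- matrix(rnorm(50 * 24), 50, 24)
  for (b in blocks) E[, b[2]] <- E[, b[1]]
  est <- estimate_consensus_correlation(E, des)
  expect_gte(est$rho, 0.98)
  expect_lte(est$rho, 0.99)
  # exchangeable runs with no block structure -> rho about 0
  E2 <- matrix(rnorm(3000 * 24), 3000, 24)
  est2 <- estimate_consensus_correlation(E2, des)
  expect_lt(abs(est2$rho), 0.05)
  # all blocks singletons: unidentifiable
  des1 <- design_spec(sample_annotations(3, 1))
  expect_error(estimate_consensus_correlation(matrix(rnorm(12 * 50), 50), des1),
               "unidentifiable")
})

test_that("consensus correlation agrees with limma's duplicateCorrelation", {
  skip_if_not_installed("limma")
  sim <- simulate_dataset(sim_config(n_proteins = 800, tau = 0.5, sigma = 0.5,
                                     missing_midpoint = -50, n_reverse = 0,
                                     n_contaminant = 0, seed = 19))
  E <- log(sim$table$intensities)
  des <- design_spec(sim$table$annotations)
  X <- model.matrix(~ 0 + des$group)
  dc <- limma::duplicateCorrelation(E, X, block = des$block)
  est <- estimate_consensus_correlation(E, des)
  expect_lt(abs(est$rho - dc$consensus.correlation), 0.05)
})

test_that("variance moderation recovers a known scaled-F prior", {
  set.seed(77)
  d <- 20; d0 <- 4; s02 <- 1
  sigma2 <- s02 * d0 / rchisq(5000, d0)
  s2 <- sigma2 * rchisq(5000, d) / d
  fit <- empirical_bayes_moderate(synthetic_fit(s2, d))
  expect_lt(abs(fit$df_prior - d0), 1)
  expect_lt(abs(fit$s2_prior - s02) / s02, 0.1)
  # invariant: s2_post = (d0 s0^2 + d s2) / (d0 + d)
  expect_equal(fit$s2_post,
               (fit$df_prior * fit$s2_prior + d * s2) / (fit$df_prior + d))
})

test_that("moderation agrees with limma::squeezeVar", {
  skip_if_not_installed("limma")
  set.seed(78)
  s2 <- 0.5 * 6 / rchisq(1000, 6) * rchisq(1000, 20) / 20
  fit <- empirical_bayes_moderate(synthetic_fit(s2, 20))
  sq <- limma::squeezeVar(s2, df = 20)
  expect_equal(fit$df_prior, sq$df.prior, tolerance = 1e-6)
  expect_equal(fit$s2_prior, sq$var.prior, tolerance = 1e-6)
  expect_equal(fit$s2_post, sq$var.post, tolerance = 1e-8)
})

test_that("moderation limits behave as closed forms predict", {
  set.seed(80)
  s2 <- rchisq(100, 10) / 10
  coefs <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "adult_response"))
  fit0 <- synthetic_fit(s2, df = 20, coefficients = coefs)
  # d0 = 0: moderated t equals the ordinary t with df = d
  none <- moderate_with_prior(fit0, df_prior = 0, s2_prior = 1)
  t_ols <- coefs[, 1] / (sqrt(s2) * fit0$stdev_unscaled)
  expect_equal(unname(none$t[, 1]), unname(t_ols), tolerance = 1e-12)
  expect_equal(none$df_total, 20)
  # d0 = Inf: every moderated variance equals s0^2, normal reference
  total <- moderate_with_prior(fit0, df_prior = Inf, s2_prior = 0.7)
  expect_equal(total$s2_post, rep(0.7, 100))
  expect_equal(unname(total$p_value[, 1]),
               unname(2 * pnorm(-abs(total$t[, 1]))), tolerance = 1e-12)
  # identical variances: the estimation itself takes the d0 = Inf branch
  same <- empirical_bayes_moderate(synthetic_fit(rep(0.5, 50), 20))
  expect_equal(same$df_prior, Inf)
  expect_equal(same$s2_post, rep(same$s2_prior, 50))
})

test_that("Benjamini-Yekutieli adjustment matches the step-up formula", {
  # hand-evaluated example: m = 4, c(4) = 25/12, all q = 1/12
  q <- adjust_benjamini_yekutieli(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(q, rep(1 / 12, 4), tolerance = 1e-12)
  # m = 1: c(1) = 1, q = p
  expect_equal(adjust_benjamini_yekutieli(0.2), 0.2)
  # property checks against an independent step-up evaluation
  set.seed(42)
  for (rep in 1:5) {
    p <- runif(sample(5:200, 1))^2
    q <- adjust_benjamini_yekutieli(p)
    expect_equal(q, by_stepup_oracle(p), tolerance = 1e-12)
    # BY dominates BH, is monotone in p, and is permutation-invariant
    expect_true(all(q >= p.adjust(p, "BH")))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(adjust_benjamini_yekutieli(p[perm]), q[perm])
  }
  expect_error(adjust_benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("significance calls use a strict threshold per contrast family", {
  pv <- matrix(c(0.001, 0.2, 0.03, 0.6), 2, 2,
               dimnames = list(NULL, c("adult_response", "fetal_response")))
  fit <- synthetic_fit(rep(0.5, 2), 20,
                       coefficients = matrix(0, 2, 2, dimnames = dimnames(pv)))
  fit <- moderate_with_prior(fit, 4, 0.5)
  fit$p_value <- pv
  fit <- adjust_results_fdr(fit)
  # families adjusted separately: column q-values equal per-column BY
  expect_equal(unname(fit$q_value[, 1]),
               unname(adjust_benjamini_yekutieli(pv[, 1])))
  sets <- call_significant(fit, alpha = 0.05)
  expect_named(sets, c("adult_response", "fetal_response"))
  # q exactly equal to alpha is not significant
  fit$q_value[1, 1] <- 0.05
  fit$q_value[2, 1] <- 0.01
  sets <- call_significant(fit, alpha = 0.05)
  expect_equal(sets$adult_response, fit$protein_id[2])
})

test_that("estimated response difference equals fetal minus adult estimates", {
  set.seed(55)
  E <- group_mean_matrix(c(0, 0.5, 1, 3), n_proteins = 40, noise_sd = 0.7)
  des <- design_spec(sample_annotations())
  for (rho in c(0, 0.5)) {
    fit <- fit_protein_models(E, des, rho = rho)
    expect_equal(fit$coefficients[, "response_difference"],
                 fit$coefficients[, "fetal_response"] -
                   fit$coefficients[, "adult_response"],
                 tolerance = 1e-12)
    expect_equal(fit$coefficients[, "total_response"],
                 (fit$coefficients[, "fetal_response"] +
                    fit$coefficients[, "adult_response"]) / 2,
                 tolerance = 1e-12)
  }
})
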