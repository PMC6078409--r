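test_that("filtering removes flagged rows and sparse proteins, and is idempotent", {
  m <- matrix(100, nrow = 5, ncol = 24)
  m[2, ] <- NA; m[2, 1:2] <- 100        # observed in 2 runs: removed
  m[3, ] <- NA; m[3, 1:3] <- 100        # observed in 3 runs: boundary, kept
  tab <- toy_table(5, intensities = m,
                   is_reverse = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                   is_contaminant = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  filt <- filter_proteins(tab, min_identifications = 3)
  expect_equal(filt$protein_id, c("P001", "P003"))
  expect_equal(filt$filter_counts, list(reverse = 1L, contaminant = 1L,
                                        min_ident = 1L))
  # a reverse flag dominates even a fully observed protein
  tab2 <- toy_table(1, intensities = matrix(100, 1, 24),
                    is_reverse = TRUE)
  expect_equal(nrow(filter_proteins(tab2)$intensities), 0)
  # idempotence
  refilt <- filter_proteins(filt, min_identifications = 3)
  expect_equal(refilt$protein_id, filt$protein_id)
  expect_equal(refilt$filter_counts, list(reverse = 0L, contaminant = 0L,
                                          min_ident = 0L))
  expect_error(filter_proteins(tab, 0), "min_identifications")
})

test_that("global epsilon imputation replaces exactly the missing cells by min/4", {
  m <- matrix(c(100, 400, NA, 800,
                200, NA, 600, 1000), nrow = 2, byrow = TRUE)
  tab <- protein_quant_table(c("P1", "P2"), m, sample_annotations(1, 1))
  imp <- impute_global_epsilon(tab)
  expect_equal(imp$epsilon, 25)  # min observed 100, /4
  expect_equal(imp$intensities[1, 3], 25)
  expect_equal(imp$intensities[2, 2], 25)
  # observed cells untouched
  expect_equal(imp$intensities[!is.na(m)], m[!is.na(m)])

  # no missing cells: matrix unchanged, epsilon still computed
  full <- protein_quant_table("P1", matrix(c(100, 200, 300, 400), 1),
                              sample_annotations(1, 1))
  imp2 <- impute_global_epsilon(full)
  expect_equal(unname(imp2$intensities[1, ]), c(100, 200, 300, 400))
  expect_equal(imp2$epsilon, 25)

  allna <- protein_quant_table("P1", matrix(NA_real_, 1, 4),
                               sample_annotations(1, 1))
  expect_error(impute_global_epsilon(allna), "epsilon is undefined")
})

test_that("imputation guarantees at least a fourfold change against observed groups", {
  # protein missing in one group, observed at m in the other: raw fold
  # difference m / epsilon >= 4 whenever m >= the global minimum
  set.seed(4)
  obs <- runif(50, 100, 1e6)
  m <- rbind(cbind(matrix(obs, 50, 2), matrix(NA, 50, 2)),
             c(100, 100, 100, 100))  # carries the global minimum
  tab <- protein_quant_table(sprintf("P%02d", 1:51), m, sample_annotations(1, 1))
  imp <- impute_global_epsilon(tab)
  fold <- imp$intensities[1:50, 1] / imp$intensities[1:50, 3]
  expect_true(all(fold >= 4))
})

test_that("mean log-shift equalizes per-run means and preserves within-run differences", {
  set.seed(9)
  raw <- matrix(rlnorm(40 * 24, 10, 1), nrow = 40)
  norm <- log_and_normalize(raw)
  expect_lt(sd(colMeans(norm)), 1e-10)
  expect_equal(unique(round(colMeans(norm), 8)), round(mean(log(raw)), 8))
  # within-run protein differences preserved exactly
  expect_equal(diff(norm[, 1]), diff(log(raw[, 1])))
  # matrix already balanced: unchanged
  expect_equal(normalize_mean_logshift(norm), norm)
  # idempotence
  expect_equal(normalize_mean_logshift(normalize_mean_logshift(log(raw))),
               normalize_mean_logshift(log(raw)))
  # doubling one run's raw values is a pure log-shift: after normalization
  # the matrices differ only by a uniform constant (the grand-mean anchor
  # moves by log(2)/n_runs), so every within- and between-run difference,
  # and hence every contrast, is unchanged
  raw2 <- raw
  raw2[, 5] <- raw2[, 5] * 2
  delta <- log_and_normalize(raw2) - norm
  expect_lt(diff(range(delta)), 1e-12)
  expect_equal(mean(delta), log(2) / 24, tolerance = 1e-10)
  expect_error(log_and_normalize(raw * 0), "positive")
})

test_that("preprocess runs the stages in order and records the bookkeeping", {
  sim <- simulate_dataset(sim_config(n_proteins = 100, seed = 3))
  prep <- preprocess(sim$table)
  expect_s3_class(prep, "PreprocessedMatrix")
  expect_false(anyNA(prep$E))
  expect_equal(prep$n_filtered_reverse, 25)
  expect_equal(prep$n_filtered_contaminant, 10)
  expect_equal(prep$epsilon,
               min(filter_proteins(sim$table)$intensities, na.rm = TRUE) / 4)
  expect_lt(sd(colMeans(prep$E)), 1e-10)
})
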