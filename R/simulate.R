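#' Configuration for the synthetic LFQ data generator
#'
#' Collects all parameters of the generative model used to emulate a
#' label-free quantification (LFQ) secretome experiment with the 2 x 2
#' (age x injury) nested replicate design. Log intensities are simulated as
#'
#'   baseline_p + group effect + biological-replicate effect + technical noise
#'
#' on the natural-log scale, exponentiated to the raw intensity scale, and
#' then left-censored at random with a probability that decreases
#' logistically in log intensity (low-abundance values go missing more
#' often, as in real LFQ data).
#'
#' Defaults describe a realistic secretome-scale experiment: ~e^14 median
#' raw intensity with a wide (sd 2 on the natural-log scale) dynamic range,
#' biological variation (tau = 0.5) clearly larger than technical noise
#' (sigma = 0.25) so the within-block correlation tau^2/(tau^2+sigma^2) =
#' 0.8, an adult injury response affecting about twice as many proteins as
#' the fetal response, and a large age-related baseline difference.
#'
#' @param n_proteins number of genuine protein rows.
#' @param n_bio biological replicates per group.
#' @param n_tech technical replicates per biological replicate.
#' @param baseline_log_mean,baseline_log_sd mean and sd of per-protein
#'   baseline log intensity (natural log).
#' @param tau sd of the biological-replicate random effect (log scale),
#'   shared by the technical replicates of one biological replicate.
#' @param sigma sd of technical noise (log scale).
#' @param effect_fractions named numeric, fractions of proteins carrying a
#'   true \code{adult} response, \code{fetal} response and \code{baseline}
#'   (fetal vs adult control) difference; memberships are drawn
#'   independently so all overlaps occur.
#' @param effect_size_dist function(n) returning n signed true log-fold
#'   changes (natural log) for effect carriers. The default draws
#'   magnitudes uniformly in [1, 4] with random sign, matching the wide
#'   dynamic range of secretome responses.
#' @param missing_midpoint log intensity at which the censoring probability
#'   is 1/2.
#' @param missing_scale logistic scale of the censoring curve (> 0);
#'   smaller values give a sharper abundance cutoff.
#' @param n_reverse,n_contaminant decoy (reversed-sequence) and contaminant
#'   rows to append, flagged as in MaxQuant output.
#' @param seed random seed (integer) used by
#'   \code{\link{simulate_dataset}}; identical seeds give identical output.
#' @return object of class \code{SimulationConfig}.
#' @export
sim_config <- function(n_proteins = 2000,
                       n_bio = 3,
                       n_tech = 2,
                       baseline_log_mean = 14,
                       baseline_log_sd = 2,
                       tau = 0.5,
                       sigma = 0.25,
                       effect_fractions = c(adult = 0.20, fetal = 0.10, baseline = 0.30),
                       effect_size_dist = default_effect_size_dist,
                       missing_midpoint = 10,
                       missing_scale = 1,
                       n_reverse = 25,
                       n_contaminant = 10,
                       seed = 1L) {
  cfg <- list(
    n_proteins = n_proteins, n_bio = n_bio, n_tech = n_tech,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    tau = tau, sigma = sigma,
    effect_fractions = effect_fractions,
    effect_size_dist = effect_size_dist,
    missing_midpoint = missing_midpoint, missing_scale = missing_scale,
    n_reverse = n_reverse, n_contaminant = n_contaminant,
    seed = seed
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param n number of effect sizes to draw.
#' @export
default_effect_size_dist <- function(n) {
  sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 1, 4)
}

validate_sim_config <- function(cfg) {
  num <- cfg[c("n_proteins", "n_bio", "n_tech", "baseline_log_mean",
               "baseline_log_sd", "tau", "sigma", "missing_midpoint",
               "missing_scale", "n_reverse", "n_contaminant")]
  vals <- unlist(num)
  if (any(!is.finite(vals))) {
    stop("non-finite simulation config value(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  }
  stopifnot(
    cfg$n_proteins >= 1, cfg$n_bio >= 1, cfg$n_tech >= 1,
    cfg$baseline_log_sd >= 0, cfg$tau >= 0, cfg$sigma >= 0,
    cfg$missing_scale > 0, cfg$n_reverse >= 0, cfg$n_contaminant >= 0
  )
  ef <- cfg$effect_fractions
  if (!all(c("adult", "fetal", "baseline") %in% names(ef))) {
    stop("effect_fractions must name 'adult', 'fetal' and 'baseline'")
  }
  if (any(!is.finite(ef)) || any(ef < 0) || any(ef > 1)) {
    stop("effect fractions must lie in [0, 1]")
  }
  if (!is.function(cfg$effect_size_dist)) stop("effect_size_dist must be a function")
  if (!is.null(cfg$seed) && !is.finite(cfg$seed)) stop("seed must be finite or NULL")
  structure(cfg, class = "SimulationConfig")
}

#' Left-censoring probability of an intensity measurement
#'
#' Probability that a cell with underlying natural-log intensity \code{x}
#' is reported missing: \code{plogis((midpoint - x) / scale)}. The curve
#' decreases monotonically in \code{x}, so lowering an underlying intensity
#' never decreases its chance of censoring.
#'
#' @param log_intensity natural-log intensity.
#' @param midpoint log intensity with 50% censoring probability.
#' @param scale logistic scale (> 0).
#' @return censoring probabilities in [0, 1].
#' @export
censoring_probability <- function(log_intensity, midpoint, scale) {
  stopifnot(scale > 0)
  stats::plogis((midpoint - log_intensity) / scale)
}

#' Simulate an LFQ protein table with known ground truth
#'
#' Generates a \code{ProteinQuantTable} following the nested design of
#' \code{\link{sample_annotations}} together with a \code{SimulationTruth}
#' table holding, per protein, the true log-fold change of each of the five
#' contrasts and its true membership flags. Group effects are parameterized
#' so the contrast identities hold exactly by construction:
#' total response = (adult response + fetal response) / 2 and
#' response difference = fetal response - adult response.
#'
#' Raw (exponentiated) intensities are reported, forcing downstream code to
#' handle the log transform; censored cells are \code{NA}. Decoy and
#' contaminant rows carry baseline-only intensities and set the
#' corresponding flags.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return list with elements \code{table} (a \code{ProteinQuantTable}) and
#'   \code{truth} (a \code{SimulationTruth} data.frame; true log-fold
#'   changes on the natural-log scale, membership logicals, and attribute
#'   \code{rho_block} = tau^2/(tau^2+sigma^2)).
#' @export
simulate_dataset <- function(config) {
  config <- validate_sim_config(unclass(config))
  if (!is.null(config$seed)) set.seed(config$seed)

  ann <- sample_annotations(config$n_bio, config$n_tech)
  des <- design_spec(ann)
  n_runs <- nrow(ann)
  p <- config$n_proteins

  baseline <- stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd)

  has_adult <- stats::runif(p) < config$effect_fractions[["adult"]]
  has_fetal <- stats::runif(p) < config$effect_fractions[["fetal"]]
  has_base <- stats::runif(p) < config$effect_fractions[["baseline"]]
  lfc_adult <- ifelse(has_adult, config$effect_size_dist(p), 0)
  lfc_fetal <- ifelse(has_fetal, config$effect_size_dist(p), 0)
  lfc_base <- ifelse(has_base, config$effect_size_dist(p), 0)

  # group-mean offsets relative to the adult-control baseline
  group_offset <- cbind(
    adult.control = 0,
    adult.injured = lfc_adult,
    fetal.control = lfc_base,
    fetal.injured = lfc_base + lfc_fetal
  )
  mu <- baseline + group_offset[, as.character(des$group), drop = FALSE]

  blocks <- levels(des$block)
  bio_eff <- matrix(stats::rnorm(p * length(blocks), 0, config$tau),
                    nrow = p, dimnames = list(NULL, blocks))
  logint <- mu + bio_eff[, as.character(des$block), drop = FALSE] +
    matrix(stats::rnorm(p * n_runs, 0, config$sigma), nrow = p)

  protein_id <- sprintf("P%05d", seq_len(p))
  n_decoy <- config$n_reverse + config$n_contaminant
  if (n_decoy > 0) {
    dec_base <- stats::rnorm(n_decoy, config$baseline_log_mean, config$baseline_log_sd)
    dec_log <- dec_base + matrix(stats::rnorm(n_decoy * n_runs, 0, config$sigma),
                                 nrow = n_decoy)
    logint <- rbind(logint, dec_log)
    protein_id <- c(
      protein_id,
      sprintf("REV_Q%04d", seq_len(config$n_reverse)),
      sprintf("CON_Q%04d", seq_len(config$n_contaminant))
    )
  }
  is_reverse <- c(rep(FALSE, p), rep(TRUE, config$n_reverse),
                  rep(FALSE, config$n_contaminant))
  is_contaminant <- c(rep(FALSE, p + config$n_reverse),
                      rep(TRUE, config$n_contaminant))

  p_miss <- censoring_probability(logint, config$missing_midpoint, config$missing_scale)
  censored <- matrix(stats::runif(length(logint)), nrow = nrow(logint)) < p_miss
  intensities <- exp(logint)
  intensities[censored] <- NA_real_
  dimnames(intensities) <- list(protein_id, ann$sample_id)

  table <- protein_quant_table(protein_id, intensities, ann,
                               is_reverse = is_reverse,
                               is_contaminant = is_contaminant)

  truth <- data.frame(
    protein_id = sprintf("P%05d", seq_len(p)),
    adult_response = lfc_adult,
    fetal_response = lfc_fetal,
    total_response = (lfc_adult + lfc_fetal) / 2,
    response_difference = lfc_fetal - lfc_adult,
    baseline_difference = lfc_base,
    sig_adult_response = lfc_adult != 0,
    sig_fetal_response = lfc_fetal != 0,
    sig_total_response = (lfc_adult + lfc_fetal) / 2 != 0,
    sig_response_difference = (lfc_fetal - lfc_adult) != 0,
    sig_baseline_difference = lfc_base != 0,
    stringsAsFactors = FALSE
  )
  attr(truth, "rho_block") <- if (config$tau == 0 && config$sigma == 0) NA_real_ else
    config$tau^2 / (config$tau^2 + config$sigma^2)
  class(truth) <- c("SimulationTruth", "data.frame")

  list(table = table, truth = truth)
}

#' Write / read a simulation ground-truth table
#'
#' Tab-separated, UTF-8, "." decimal separator; round-trips losslessly up
#' to the 15 significant digits written. An empty truth (0 proteins) yields
#' a header-only file.
#'
#' @param truth a \code{SimulationTruth} data.frame.
#' @param path destination / source file path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  utils::write.table(as.data.frame(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  truth <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(protein_id = "character"))
  class(truth) <- c("SimulationTruth", "data.frame")
  truth
}
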