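#' Configuration for an end-to-end pipeline run
#'
#' A run takes its input either from a protein-table TSV plus annotations
#' (\code{table_path}) or from the synthetic generator
#' (\code{simulation}); exactly one must be given.
#'
#' @param table_path path to a proteinGroups-style TSV, or \code{NULL}.
#' @param annotations sample annotation data.frame (required with
#'   \code{table_path}; defaults to the standard 24-run design).
#' @param simulation a \code{\link{sim_config}}, or \code{NULL}.
#' @param min_identifications minimum runs quantified per protein.
#' @param alpha significance threshold on q-values.
#' @param logfc_base base of the reported log-fold changes.
#' @param output_dir directory for all output files, or \code{NULL} to
#'   return results without writing.
#' @param seed seed overriding the simulation config's seed, or
#'   \code{NULL}.
#' @return object of class \code{RunConfig}.
#' @export
run_config <- function(table_path = NULL, annotations = sample_annotations(),
                       simulation = NULL, min_identifications = 3,
                       alpha = 0.05, logfc_base = 2, output_dir = NULL,
                       seed = NULL) {
  if (is.null(table_path) == is.null(simulation)) {
    stop("give exactly one of table_path or simulation")
  }
  stopifnot(alpha > 0, alpha < 1, logfc_base > 1, min_identifications >= 1)
  structure(
    list(table_path = table_path, annotations = annotations,
         simulation = simulation, min_identifications = min_identifications,
         alpha = alpha, logfc_base = logfc_base, output_dir = output_dir,
         seed = seed),
    class = "RunConfig"
  )
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full differential-response pipeline
#'
#' Executes filter, impute, log/normalize, consensus-correlation
#' estimation, per-protein GLS fits, empirical-Bayes moderation,
#' Benjamini-Yekutieli adjustment, significance calls, the four-test Venn
#' decomposition and the Spearman sample-correlation summary, logging one
#' line per stage. With an \code{output_dir} all tables plus a JSON run
#' summary are written; identical config and seed give identical outputs.
#'
#' @param config a \code{\link{run_config}}.
#' @param quiet suppress per-stage log lines.
#' @return (invisibly) list with \code{table}, \code{truth} (if
#'   simulated), \code{prep}, \code{rho}, \code{results},
#'   \code{significant}, \code{partition}, \code{partition_summary},
#'   \code{correlation} and \code{summary} (the JSON-ready run summary).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (!quiet) message(sprintf(...))

  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    if (!is.null(config$seed)) sim_cfg$seed <- config$seed
    sim <- with_stage("simulate", simulate_dataset(sim_cfg))
    table <- sim$table
    truth <- sim$truth
    say("simulate: %d proteins x %d runs", nrow(table$intensities),
        ncol(table$intensities))
  } else {
    table <- with_stage("read", read_protein_groups(config$table_path,
                                                    config$annotations))
    truth <- NULL
    say("read: %d proteins x %d runs from %s", nrow(table$intensities),
        ncol(table$intensities), config$table_path)
  }

  prep <- with_stage("preprocess", preprocess(table, config$min_identifications))
  say("preprocess: kept %d proteins (removed %d reverse, %d contaminant, %d sparse); epsilon = %.4g",
      nrow(prep$E), prep$n_filtered_reverse, prep$n_filtered_contaminant,
      prep$n_filtered_min_ident, prep$epsilon)

  design <- with_stage("design", design_spec(prep$annotations))
  rho <- with_stage("consensus_correlation",
                    estimate_consensus_correlation(prep, design))
  say("consensus correlation: rho_block = %.4f", rho$rho)

  results <- with_stage("fit", fit_protein_models(prep, design, rho = rho))
  results <- with_stage("moderate", empirical_bayes_moderate(results))
  results <- with_stage("adjust", adjust_results_fdr(results))
  sig <- with_stage("call", call_significant(results, config$alpha))
  say("fit: d0 = %.3g, s0^2 = %.3g; significant (q < %g): %s",
      results$df_prior, results$s2_prior, config$alpha,
      paste(sprintf("%s=%d", names(sig), lengths(sig)), collapse = ", "))

  partition <- with_stage("decompose", venn_partition(
    total = sig$total_response, fetal = sig$fetal_response,
    adult = sig$adult_response, difference = sig$response_difference
  ))
  psummary <- summarize_partition(partition)
  say("decompose: union of four response sets = %d proteins",
      sum(partition$counts))

  correlation <- with_stage("correlate", spearman_matrix(prep))
  say("correlate: %d x %d Spearman matrix", nrow(correlation), ncol(correlation))

  summary <- list(
    n_proteins_input = nrow(table$intensities),
    n_proteins_analyzed = nrow(prep$E),
    n_filtered_reverse = prep$n_filtered_reverse,
    n_filtered_contaminant = prep$n_filtered_contaminant,
    n_filtered_min_ident = prep$n_filtered_min_ident,
    epsilon = prep$epsilon,
    rho_block = rho$rho,
    df_prior = results$df_prior,
    s2_prior = results$s2_prior,
    alpha = config$alpha,
    significant_counts = as.list(lengths(sig)),
    venn_regions = as.list(partition$counts)
  )

  out <- list(table = table, truth = truth, prep = prep, rho = rho,
              results = results, significant = sig, partition = partition,
              partition_summary = psummary, correlation = correlation,
              summary = summary)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$output_dir, f)
    with_stage("write", {
      write_protein_groups(table, p("protein_groups.tsv"))
      if (!is.null(truth)) write_truth(truth, p("simulation_truth.tsv"))
      utils::write.table(
        data.frame(protein_id = rownames(prep$E), prep$E, check.names = FALSE),
        p("preprocessed_matrix.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      write_results(results, p("contrast_results.tsv"),
                    logfc_base = config$logfc_base)
      write_partition(partition, p("venn_partition.tsv"))
      write_correlation_matrix(correlation, p("sample_correlation.tsv"))
      jsonlite::write_json(summary, p("run_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    say("wrote outputs to %s", config$output_dir)
  }
  invisible(out)
}
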