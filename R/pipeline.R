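#' Run the full pipeline on simulated cohorts
#'
#' Generates two microarray series (RA/OA/HC), optionally an RNA-seq series
#' (RA/HC), and the paired prediction sources; computes per-series
#' differential expression; and runs the candidate-selection cascade
#' ([select_candidates()]) with the OA-vs-HC false-positive filter taken
#' from the first microarray series.
#'
#' @param config A [sim_config()] object.
#' @param comparison RA-vs-control comparison to select on (`"RA_vs_HC"` or
#'   `"RA_vs_OA"`).
#' @param include_rnaseq Also generate and analyse an RNA-seq series (its DE
#'   table is returned but, being a different platform, it is not mixed into
#'   the microarray consistency filter).
#' @param enforce_p,use_q,min_abs_lfc,max_p Passed to [select_candidates()].
#' @return List: `result` (from [select_candidates()]), `truth`,
#'   `consensus_map`, `de_tables`, `oa_hc_records`, and `rnaseq_de` when
#'   requested.
#' @export
run_simulated_pipeline <- function(config, comparison = "RA_vs_HC",
                                   include_rnaseq = FALSE,
                                   enforce_p = TRUE, use_q = FALSE,
                                   min_abs_lfc = 1.0, max_p = 0.05) {
  sim1 <- gen_microarray_series(config, "sim_array_1")
  sim2 <- gen_microarray_series(config, "sim_array_2")
  truth <- sim1$truth
  preds <- gen_target_dbs(truth, config)
  consensus_map <- consensus_all(preds)

  de_tables <- list(
    sim_array_1 = run_de(sim1$series, comparison),
    sim_array_2 = run_de(sim2$series, comparison)
  )
  oa_hc <- run_de(sim1$series, "OA_vs_HC")

  result <- select_candidates(
    de_tables, config$mirna_table, consensus_map,
    oa_hc_records = oa_hc, min_abs_lfc = min_abs_lfc, max_p = max_p,
    use_q = use_q, enforce_p = enforce_p
  )
  out <- list(result = result, truth = truth, consensus_map = consensus_map,
              de_tables = de_tables, oa_hc_records = oa_hc)
  if (include_rnaseq) {
    simr <- gen_rnaseq_series(config, "sim_rnaseq_1")
    out$rnaseq_de <- run_de(simr$series, "RA_vs_HC", pseudocount = 0.5)
    out$rnaseq_series <- simr$series
  }
  out
}

#' Evaluate called pairs against simulation truth
#'
#' Sensitivity is the fraction of recoverable true targets that were
#' called, where "recoverable" means present in the consensus map the
#' pipeline ran with: targets the simulated prediction catalogues failed to
#' carry are misses of the (simulated) prediction step, not of the
#' selection cascade under evaluation. The false-discovery proportion is
#' the fraction of called genes that are not true targets.
#'
#' @param pairs Pair table (e.g. `result$strict_pairs`).
#' @param truth A [sim_truth()] object.
#' @param consensus_map The consensus map the pipeline used.
#' @return List with `sensitivity`, `fdp`, `n_called`, `n_recoverable`,
#'   `n_true`.
#' @export
evaluate_recovery <- function(pairs, truth, consensus_map) {
  true_genes <- unlist(truth$true_targets, use.names = FALSE)
  recoverable <- intersect(true_genes,
                           unlist(consensus_map, use.names = FALSE))
  called <- pairs$gene
  tp <- intersect(called, true_genes)
  list(
    sensitivity = if (length(recoverable))
      length(intersect(called, recoverable)) / length(recoverable)
    else NA_real_,
    fdp = if (length(called)) 1 - length(tp) / length(called) else 0,
    n_called = length(called),
    n_recoverable = length(recoverable),
    n_true = length(true_genes)
  )
}

#' Write a pair-candidate table
#'
#' Tab-separated with columns `gene`, `mirnas`, `tier`, `sign`,
#' `anticorrelated`.
#'
#' @param pairs Pair table from [select_candidates()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
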