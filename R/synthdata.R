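# Deterministic sub-stream seeding: every generator derives its RNG seed
# from (config seed, label), so adding a generator never perturbs the draws
# of another and identical (config, seed) always reproduce bit-identical
# output.
.seed_for <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h * 69069 + seed) %% 2147483647)
}

#' Configuration for the synthetic multi-cohort generator
#'
#' Encodes the study design the integration pipeline assumes: three sample
#' groups (RA cases, OA disease controls, HC healthy controls), a curated
#' set of dysregulated miRNAs whose true target genes shift in RA only and
#' in the direction opposite the miRNA, and a shared "arthritis signature"
#' gene subset shifted in both RA and OA versus HC — the genes a naive
#' RA-vs-HC comparison mistakes for RA-specific and that the
#' control-vs-control filter must remove.
#'
#' @param n_genes Number of genes (must accommodate all targets plus the
#'   signature subset).
#' @param samples_per_group Named integer vector `c(RA=, OA=, HC=)`.
#' @param effect_delta Log2 shift applied to true-target genes in RA; may be
#'   0 for a null simulation.
#' @param shared_oa_hc_delta Log2 shift applied to arthritis-signature genes
#'   in both RA and OA versus HC. The default (2, i.e. 4-fold) makes the
#'   shared signature clearly detectable so the false-positive filter is
#'   exercised rather than dodged.
#' @param noise_sd Per-observation Gaussian sd on the log2 scale
#'   (microarray).
#' @param mirna_table Curated miRNA table (defaults to the bundled one).
#' @param targets_per_mirna True targets per miRNA (disjoint across miRNAs).
#' @param n_fp_signature Number of arthritis-signature genes.
#' @param db_sensitivity Probability a true target appears in each
#'   prediction source.
#' @param db_fp_rate Expected decoy genes per miRNA per source (Poisson).
#' @param nb_dispersion Negative-binomial dispersion for RNA-seq counts
#'   (`size = 1/nb_dispersion`).
#' @param gene_length_range Gene length interval in bp.
#' @param library_size Total fragments per RNA-seq sample.
#' @param seed Integer master seed.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_genes = 1000,
                       samples_per_group = c(RA = 10, OA = 10, HC = 10),
                       effect_delta = 1.5,
                       shared_oa_hc_delta = 2.0,
                       noise_sd = 0.5,
                       mirna_table = load_fixture_table("mirna_table"),
                       targets_per_mirna = 20,
                       n_fp_signature = 50,
                       db_sensitivity = 0.9,
                       db_fp_rate = 10,
                       nb_dispersion = 0.1,
                       gene_length_range = c(500, 3000),
                       library_size = 2e7,
                       seed = 1) {
  stopifnot(n_genes >= 1, targets_per_mirna >= 1, n_fp_signature >= 0,
            all(samples_per_group >= 1),
            all(names(samples_per_group) %in% c("RA", "OA", "HC")),
            noise_sd > 0, effect_delta >= 0, shared_oa_hc_delta >= 0,
            db_sensitivity >= 0, db_sensitivity <= 1, db_fp_rate >= 0,
            nb_dispersion > 0, length(gene_length_range) == 2L,
            gene_length_range[1] > 0,
            gene_length_range[2] >= gene_length_range[1],
            library_size > 0, length(seed) == 1L)
  if (!all(mirna_table$direction %in% c("up", "down"))) {
    stop("mirna_table directions must be 'up' or 'down'", call. = FALSE)
  }
  need <- nrow(mirna_table) * targets_per_mirna + n_fp_signature
  if (n_genes < need) {
    stop("n_genes (", n_genes, ") too small for ", need,
         " target + signature genes", call. = FALSE)
  }
  structure(list(
    n_genes = n_genes, samples_per_group = samples_per_group,
    effect_delta = effect_delta, shared_oa_hc_delta = shared_oa_hc_delta,
    noise_sd = noise_sd, mirna_table = mirna_table,
    targets_per_mirna = targets_per_mirna, n_fp_signature = n_fp_signature,
    db_sensitivity = db_sensitivity, db_fp_rate = db_fp_rate,
    nb_dispersion = nb_dispersion, gene_length_range = gene_length_range,
    library_size = library_size, seed = as.integer(seed)
  ), class = "SimConfig")
}

#' Ground truth of a simulated study
#'
#' Derived deterministically from the configuration (its own RNG
#' sub-stream), so every generator called with the same config shares one
#' truth: disjoint true-target sets per miRNA, each target's effect sign
#' (opposite its miRNA's direction), the arthritis-signature gene set, and
#' per-gene baseline log2 means.
#'
#' @param config A [sim_config()] object.
#' @return List of class `SimTruth`: `true_targets` (named list
#'   `mirna_id -> genes`), `effect_sign` (named numeric, +1/-1),
#'   `fp_signature_genes`, `baseline_means` (named numeric, log2),
#'   `gene_lengths` (named, bp), `seed`.
#' @export
sim_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  set.seed(.seed_for(config$seed, "truth"))
  mt <- config$mirna_table
  n_target <- nrow(mt) * config$targets_per_mirna
  special <- sample(genes, n_target + config$n_fp_signature)
  target_genes <- special[seq_len(n_target)]
  fp_genes <- special[seq_len(config$n_fp_signature) + n_target]
  true_targets <- split(target_genes,
                        rep(mt$mirna_id, each = config$targets_per_mirna))
  true_targets <- true_targets[mt$mirna_id]
  dir_sign <- .dir_to_sign(mt$direction)
  effect_sign <- stats::setNames(
    rep(-dir_sign, each = config$targets_per_mirna), target_genes)
  baseline <- stats::setNames(stats::runif(config$n_genes, 6, 12), genes)
  lengths <- stats::setNames(
    round(stats::runif(config$n_genes, config$gene_length_range[1],
                       config$gene_length_range[2])), genes)
  structure(list(
    true_targets = true_targets, effect_sign = effect_sign,
    fp_signature_genes = fp_genes, baseline_means = baseline,
    gene_lengths = lengths, seed = config$seed
  ), class = "SimTruth")
}

# Per-gene, per-group true log2 mean: baseline, plus the miRNA-driven shift
# in RA only, plus the shared arthritis signature in RA and OA.
.group_means <- function(config, truth, group) {
  mu <- truth$baseline_means
  if (group == "RA") {
    tg <- names(truth$effect_sign)
    mu[tg] <- mu[tg] + truth$effect_sign * config$effect_delta
  }
  if (group %in% c("RA", "OA")) {
    fp <- truth$fp_signature_genes
    mu[fp] <- mu[fp] + config$shared_oa_hc_delta
  }
  mu
}

#' Generate a microarray-kind expression series
#'
#' Log2 intensities: per-gene baseline plus group effects plus i.i.d.
#' Gaussian noise. True targets shift by `effect_sign * effect_delta` in RA
#' only; arthritis-signature genes shift by `shared_oa_hc_delta` in RA and
#' OA. Bit-identical output for identical (config, series_id).
#'
#' @param config A [sim_config()] object.
#' @param series_id Label for the simulated series.
#' @param groups Groups to simulate, a subset of `RA`, `OA`, `HC` present in
#'   `config$samples_per_group`.
#' @return List with `series` (an [expression_series()]) and `truth`
#'   (a [sim_truth()]).
#' @export
gen_microarray_series <- function(config, series_id,
                                  groups = names(config$samples_per_group)) {
  stopifnot(inherits(config, "SimConfig"))
  bad <- setdiff(groups, c("RA", "OA", "HC"))
  if (length(bad)) {
    stop("invalid group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(groups, names(config$samples_per_group))
  if (length(missing)) {
    stop("no sample count configured for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  truth <- sim_truth(config)
  set.seed(.seed_for(config$seed, paste0("microarray:", series_id)))
  cols <- list(); labels <- character(0)
  for (g in groups) {
    n <- config$samples_per_group[[g]]
    mu <- .group_means(config, truth, g)
    block <- matrix(stats::rnorm(config$n_genes * n, mean = mu,
                                 sd = config$noise_sd),
                    nrow = config$n_genes, ncol = n)
    cols[[g]] <- block
    labels <- c(labels, rep(g, n))
  }
  values <- do.call(cbind, cols)
  rownames(values) <- names(truth$baseline_means)
  colnames(values) <- sprintf("%s_%s_%02d", series_id, labels,
                              unlist(lapply(groups, function(g)
                                seq_len(config$samples_per_group[[g]]))))
  series <- expression_series(series_id, "microarray", values,
                              stats::setNames(labels, colnames(values)))
  list(series = series, truth = truth)
}

#' Generate an RNA-seq-kind expression series (FPKM)
#'
#' Per-gene fragment counts are drawn negative-binomially around the
#' exponentiated group log2 means scaled by gene length and library size
#' (`size = 1/nb_dispersion`), then converted to FPKM as
#' `count / (gene_length_kb * library_size_millions)`. Only the RA and HC
#' groups are simulated (the RNA-seq cohort design). Deterministic given
#' (config, series_id).
#'
#' @inheritParams gen_microarray_series
#' @return List with `series` and `truth` as in [gen_microarray_series()].
#' @export
gen_rnaseq_series <- function(config, series_id) {
  stopifnot(inherits(config, "SimConfig"))
  groups <- c("RA", "HC")
  missing <- setdiff(groups, names(config$samples_per_group))
  if (length(missing)) {
    stop("no sample count configured for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  truth <- sim_truth(config)
  len_kb <- truth$gene_lengths / 1000
  lib_m <- config$library_size / 1e6
  if (lib_m <= 0) stop("zero library size", call. = FALSE)
  set.seed(.seed_for(config$seed, paste0("rnaseq:", series_id)))
  cols <- list(); labels <- character(0)
  for (g in groups) {
    n <- config$samples_per_group[[g]]
    mean_fpkm <- 2^.group_means(config, truth, g)
    mean_count <- mean_fpkm * len_kb * lib_m
    block <- matrix(stats::rnbinom(config$n_genes * n,
                                   mu = mean_count,
                                   size = 1 / config$nb_dispersion),
                    nrow = config$n_genes, ncol = n)
    cols[[g]] <- block / (len_kb * lib_m)
    labels <- c(labels, rep(g, n))
  }
  values <- do.call(cbind, cols)
  rownames(values) <- names(truth$baseline_means)
  colnames(values) <- sprintf("%s_%s_%02d", series_id, labels,
                              unlist(lapply(groups, function(g)
                                seq_len(config$samples_per_group[[g]]))))
  series <- expression_series(series_id, "rnaseq", values,
                              stats::setNames(labels, colnames(values)))
  list(series = series, truth = truth)
}

#' Generate a pair of synthetic target-prediction sources
#'
#' Emulates two independent prediction catalogues: each true target enters
#' each source with probability `db_sensitivity`, each source adds
#' Poisson(`db_fp_rate`) decoy genes per miRNA, and miRNAs whose curated
#' record lacks a first-source target count (`n_source_a` is `NA`) are
#' omitted from source A entirely, exercising the single-source fallback of
#' [consensus()]. Arthritis-signature genes are planted in both sources
#' (each under one randomly chosen miRNA) so they reach candidacy and the
#' control-vs-control filter is actually load-bearing downstream.
#'
#' @param truth A [sim_truth()] object.
#' @param config The [sim_config()] that produced it.
#' @return List with `source_a`, `source_b` (named lists
#'   `mirna_id -> genes`) and `universe` (all simulated genes).
#' @export
gen_target_dbs <- function(truth, config) {
  stopifnot(inherits(truth, "SimTruth"), inherits(config, "SimConfig"))
  set.seed(.seed_for(config$seed, "target_dbs"))
  genes <- names(truth$baseline_means)
  mt <- config$mirna_table
  absent_a <- mt$mirna_id[is.na(mt$n_source_a)]
  draw_source <- function() {
    out <- lapply(mt$mirna_id, function(m) {
      tg <- truth$true_targets[[m]]
      kept <- tg[stats::runif(length(tg)) < config$db_sensitivity]
      n_decoy <- stats::rpois(1, config$db_fp_rate)
      decoys <- sample(setdiff(genes, tg), n_decoy)
      sort(unique(c(kept, decoys)))
    })
    stats::setNames(out, mt$mirna_id)
  }
  source_a <- draw_source()
  source_b <- draw_source()
  fp <- truth$fp_signature_genes
  if (length(fp)) {
    host <- sample(mt$mirna_id, length(fp), replace = TRUE)
    for (i in seq_along(fp)) {
      source_a[[host[[i]]]] <- sort(unique(c(source_a[[host[[i]]]], fp[[i]])))
      source_b[[host[[i]]]] <- sort(unique(c(source_b[[host[[i]]]], fp[[i]])))
    }
  }
  source_a[absent_a] <- NULL
  list(source_a = source_a, source_b = source_b, universe = genes)
}

#' Write a simulation truth table
#'
#' Tab-separated columns `gene`, `mirna` (empty for non-targets),
#' `effect_sign` (0 for non-targets), `is_fp_signature`.
#'
#' @param truth A [sim_truth()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  genes <- names(truth$baseline_means)
  gene_mirna <- stats::setNames(rep("", length(genes)), genes)
  for (m in names(truth$true_targets)) {
    gene_mirna[truth$true_targets[[m]]] <- m
  }
  sign <- stats::setNames(rep(0, length(genes)), genes)
  sign[names(truth$effect_sign)] <- truth$effect_sign
  out <- data.frame(
    gene = genes, mirna = unname(gene_mirna), effect_sign = unname(sign),
    is_fp_signature = genes %in% truth$fp_signature_genes,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
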