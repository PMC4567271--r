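test_that("simulation config validates its invariants", {
  expect_error(sim_config(n_genes = 10), "too small")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(db_sensitivity = 1.5), "db_sensitivity")
  mt <- load_fixture_table("mirna_table")
  mt$direction[1] <- "sideways"
  expect_error(sim_config(mirna_table = mt), "up' or 'down")
})

test_that("simulated truth is disjoint, sign-consistent and config-determined", {
  config <- small_config(seed = 9)
  truth <- sim_truth(config)
  all_targets <- unlist(truth$true_targets, use.names = FALSE)
  expect_identical(anyDuplicated(all_targets), 0L)
  expect_length(all_targets, 14L * config$targets_per_mirna)
  expect_length(intersect(all_targets, truth$fp_signature_genes), 0L)

  dirs <- mirna_directions(config$mirna_table)
  for (m in names(truth$true_targets)) {
    expected <- if (dirs[[m]] == "up") -1 else 1
    expect_true(all(truth$effect_sign[truth$true_targets[[m]]] == expected))
  }
  expect_identical(sim_truth(config), truth)
})

test_that("microarray generator honours shape, determinism and group effects", {
  config <- small_config(seed = 2)
  sim <- gen_microarray_series(config, "arr")
  expect_equal(dim(sim$series$values),
               c(400, sum(config$samples_per_group)))
  expect_equal(as.integer(table(sim$series$groups)[c("RA", "OA", "HC")]),
               c(10L, 10L, 10L))

  again <- gen_microarray_series(config, "arr")
  expect_identical(again$series$values, sim$series$values)
  other <- gen_microarray_series(config, "arr2")
  expect_false(identical(other$series$values, sim$series$values))
  expect_identical(other$truth, sim$truth)  # truth shared across series

  expect_error(gen_microarray_series(config, "x", groups = "XX"),
               "invalid group")

  # injected shifts recovered on average
  truth <- sim$truth
  vals <- sim$series$values
  ra <- sim$series$groups == "RA"; hc <- sim$series$groups == "HC"
  oa <- sim$series$groups == "OA"
  tg <- names(truth$effect_sign)
  est <- rowMeans(vals[tg, ra]) - rowMeans(vals[tg, hc])
  expect_equal(mean(est * truth$effect_sign), config$effect_delta,
               tolerance = 0.1)
  fp <- truth$fp_signature_genes
  expect_equal(mean(rowMeans(vals[fp, oa]) - rowMeans(vals[fp, hc])),
               config$shared_oa_hc_delta, tolerance = 0.15)
})

test_that("null simulation is calibrated at the nominal type-I rate", {
  config <- small_config(effect_delta = 0, shared_oa_hc_delta = 0,
                         n_fp_signature = 0, seed = 31)
  sim <- gen_microarray_series(config, "null", groups = c("RA", "HC"))
  de <- run_de(sim$series, "RA_vs_HC")
  expect_equal(mean(de$logFC), 0, tolerance = 0.05)
  expect_gt(mean(de$p < 0.05), 0.02)
  expect_lt(mean(de$p < 0.05), 0.09)
})

test_that("RNA-seq generator produces finite non-negative FPKM deterministically", {
  config <- small_config(seed = 4)
  sim <- gen_rnaseq_series(config, "rna")
  vals <- sim$series$values
  expect_true(all(is.finite(vals)))
  expect_true(all(vals >= 0))
  expect_identical(sim$series$kind, "rnaseq")
  expect_setequal(unique(sim$series$groups), c("RA", "HC"))
  expect_identical(gen_rnaseq_series(config, "rna")$series$values, vals)

  # FPKM group ratio approaches the injected log2 effect
  config8 <- small_config(seed = 4, effect_delta = 3, nb_dispersion = 1e-4,
                          samples_per_group = c(RA = 30, OA = 2, HC = 30))
  sim8 <- gen_rnaseq_series(config8, "rna8")
  de <- run_de(sim8$series, "RA_vs_HC")
  tg <- names(sim8$truth$effect_sign)
  est <- de$logFC[match(tg, de$gene)] * sim8$truth$effect_sign
  expect_equal(mean(est), 3, tolerance = 0.05)
})

test_that("injected RNA-seq effects are recovered by the DE filter", {
  config <- small_config(seed = 12, effect_delta = 3)
  sim <- gen_rnaseq_series(config, "rna")
  de <- run_de(sim$series, "RA_vs_HC")
  hits <- filter_de(de, min_abs_lfc = 1, max_p = 0.05, use_q = TRUE)$gene
  tg <- names(sim$truth$effect_sign)
  expect_gte(length(intersect(hits, tg)) / length(tg), 0.8)
})

test_that("prediction sources respect sensitivity, decoys and the fallback miRNA", {
  config <- small_config(db_sensitivity = 1, db_fp_rate = 0,
                         n_fp_signature = 0, seed = 6)
  truth <- sim_truth(config)
  dbs <- gen_target_dbs(truth, config)
  cons <- consensus_all(dbs)
  # noiseless case: consensus recovers the truth exactly
  for (m in names(truth$true_targets)) {
    expect_setequal(cons[[m]], truth$true_targets[[m]])
  }
  # the curated miRNA with no source-A record exercises the fallback
  expect_false("miR-34a-3p" %in% names(dbs$source_a))
  expect_true(attr(cons, "used_fallback")[["miR-34a-3p"]])
  expect_false(any(attr(cons, "used_fallback")[names(cons) != "miR-34a-3p"]))

  # arthritis-signature genes are planted in both sources
  config_fp <- small_config(seed = 6)
  truth_fp <- sim_truth(config_fp)
  dbs_fp <- gen_target_dbs(truth_fp, config_fp)
  cons_fp <- unlist(consensus_all(dbs_fp), use.names = FALSE)
  expect_true(all(truth_fp$fp_signature_genes %in% cons_fp))
})

test_that("consensus size follows the two-source binomial expectation", {
  sizes <- numeric(0)
  for (seed in 1:60) {
    config <- small_config(db_sensitivity = 0.8, db_fp_rate = 0,
                           n_fp_signature = 0, seed = seed)
    truth <- sim_truth(config)
    cons <- consensus_all(gen_target_dbs(truth, config))
    fallback <- attr(cons, "used_fallback")
    sizes <- c(sizes, lengths(cons[!fallback]))
  }
  # independent inclusion in each source: E|consensus| = 0.64 * targets
  expect_equal(mean(sizes), 0.64 * 10, tolerance = 0.15)
})

test_that("truth tables serialise with target and signature annotation", {
  config <- small_config(seed = 5)
  truth <- sim_truth(config)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(truth, f)
  tab <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(nrow(tab), config$n_genes)
  expect_equal(sum(tab$is_fp_signature), config$n_fp_signature)
  expect_setequal(tab$gene[tab$mirna != ""],
                  unlist(truth$true_targets, use.names = FALSE))
  expect_true(all(tab$effect_sign[tab$mirna == ""] == 0))
})
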