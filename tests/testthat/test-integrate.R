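test_that("control-vs-control removal partitions the candidate set", {
  oa_hc <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    comparison = "OA_vs_HC",
    logFC = c(2.0, 0.5, -1.5, 1.2),
    p = c(0.01, 0.01, 0.02, 0.30)
  )
  cand <- c("g1", "g2", "g3", "g5", "g6")
  res <- remove_control_fp(cand, oa_hc)
  expect_identical(res$removed, c("g1", "g3"))
  expect_identical(res$kept, c("g2", "g5", "g6"))
  expect_setequal(c(res$kept, res$removed), cand)
  expect_length(intersect(res$kept, res$removed), 0L)

  none <- remove_control_fp(cand, oa_hc[oa_hc$p > 0.2, , drop = FALSE])
  expect_identical(none$kept, sort(cand))

  wrong <- oa_hc; wrong$comparison <- "RA_vs_HC"
  expect_error(remove_control_fp(cand, wrong), "OA_vs_HC")
})

test_that("strict consistency needs threshold and sign agreement everywhere", {
  per_series <- list(
    s1 = data.frame(gene = c("up", "conflict", "weak", "partial"),
                    logFC = c(1.5, 1.5, 0.8, 1.5)),
    s2 = data.frame(gene = c("up", "conflict", "weak", "partial"),
                    logFC = c(1.2, -1.2, 0.9, 0.8))
  )
  out <- strict_consistency(per_series)
  expect_identical(out$gene, "up")
  expect_identical(out$sign, 1)
  expect_error(strict_consistency(per_series["s1"]), ">= 2 series")

  # a gene missing from one series cannot enter the strict tier
  missing <- list(
    s1 = data.frame(gene = c("a", "b"), logFC = c(2, 2)),
    s2 = data.frame(gene = "a", logFC = 2)
  )
  expect_identical(strict_consistency(missing)$gene, "a")
})

test_that("relaxed consistency admits one qualifying series without sign conflict", {
  per_series <- list(
    s1 = data.frame(gene = c("one", "conflict", "none", "weakqual"),
                    logFC = c(1.597, 1.5, 0.8, 0.3)),
    s2 = data.frame(gene = c("one", "conflict", "none", "weakqual"),
                    logFC = c(0.879, -1.5, 0.9, 1.2)),
    s3 = data.frame(gene = c("one", "conflict", "none", "weakqual"),
                    logFC = c(0.429, 0.2, 0.5, 0.4))
  )
  out <- relaxed_consistency(per_series)
  # sub-threshold sign disagreement is ignored; conflicting qualifying
  # series are not
  expect_setequal(out$gene, c("one", "weakqual"))
  expect_identical(out$sign[out$gene == "one"], 1)
})

test_that("strict output is always a subset of relaxed output", {
  set.seed(7)
  for (rep in 1:20) {
    genes <- paste0("g", 1:30)
    per_series <- lapply(1:3, function(i) {
      data.frame(gene = genes, logFC = rnorm(30, sd = 1.2))
    })
    names(per_series) <- paste0("s", 1:3)
    s <- strict_consistency(per_series)
    r <- relaxed_consistency(per_series)
    expect_true(all(s$gene %in% r$gene))
    if (nrow(s)) {
      expect_identical(s$sign, r$sign[match(s$gene, r$gene)])
    }
  }
})

test_that("anticorrelation keeps only direction-opposed edges", {
  mt <- load_fixture_table("mirna_table")
  genes <- data.frame(gene = c("gUp", "gDown", "gBoth"),
                      sign = c(1, -1, 1))
  g2m <- list(
    gUp = "miR-30a",            # down-regulated miRNA, up gene: keep
    gDown = "miR-203a",         # up miRNA, down gene: keep
    gBoth = c("miR-30a", "miR-203a")  # second edge discordant: drop edge
  )
  pairs <- anticorrelated_pairs(genes, mt, g2m)
  expect_setequal(pairs$gene, c("gUp", "gDown", "gBoth"))
  expect_identical(pairs$mirnas[pairs$gene == "gBoth"], "miR-30a")
  expect_true(all(pairs$anticorrelated))

  # up gene with only an up miRNA: gene dropped entirely
  up_up <- anticorrelated_pairs(
    data.frame(gene = "g", sign = 1), mt, list(g = "miR-203a"))
  expect_identical(nrow(up_up), 0L)

  expect_error(
    anticorrelated_pairs(data.frame(gene = "g", sign = 1), mt,
                         list(g = "miR-fake")),
    "absent from the curated table")
  expect_error(
    anticorrelated_pairs(data.frame(gene = "g", sign = 1), mt, list()),
    "no candidate miRNA")
})

test_that("every emitted pair satisfies the sign identity exactly", {
  mt <- load_fixture_table("mirna_table")
  dirs <- mirna_directions(mt)
  for (fixture in c("ra_hc_microarray", "ra_oa_microarray")) {
    ev <- fixture_evidence(load_fixture_table(fixture))
    genes <- relaxed_consistency(ev$per_series)
    pairs <- anticorrelated_pairs(genes, mt, ev$gene_to_mirnas)
    for (i in seq_len(nrow(pairs))) {
      for (m in split_mirnas(pairs$mirnas[i])[[1]]) {
        expect_identical(pairs$sign[i],
                         -ifelse(dirs[[m]] == "up", 1, -1))
      }
    }
  }
})

test_that("selection cascade is invariant to row and series order", {
  config <- small_config(seed = 3)
  run <- run_simulated_pipeline(config)

  shuffled <- lapply(run$de_tables, function(df) {
    df[sample(nrow(df)), , drop = FALSE]
  })
  shuffled <- rev(shuffled)
  res2 <- select_candidates(shuffled, config$mirna_table,
                            run$consensus_map,
                            oa_hc_records = run$oa_hc_records)
  expect_identical(res2$strict_pairs, run$result$strict_pairs)
  expect_identical(res2$relaxed_pairs, run$result$relaxed_pairs)
  expect_identical(res2$fp_removed, run$result$fp_removed)
})

test_that("empty consensus map gives empty output without error", {
  config <- small_config(seed = 3)
  de <- data.frame(gene = "g00001", series_id = "s", comparison = "RA_vs_HC",
                   logFC = 2, p = 0.01, q = 0.01)
  res <- select_candidates(list(s1 = de, s2 = de), config$mirna_table,
                           list())
  expect_identical(nrow(res$strict_pairs), 0L)
  expect_identical(nrow(res$relaxed_pairs), 0L)
})
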