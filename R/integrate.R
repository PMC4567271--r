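#' Remove control-vs-control false positives
#'
#' A gene differentially expressed between the two control conditions (OA vs
#' HC) reflects a shared arthritis signature rather than an RA-specific
#' effect, and is removed from the candidate list.
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param oa_hc_records [run_de()] output for the `OA_vs_HC` comparison.
#' @param min_abs_lfc,max_p,use_q Thresholds passed to [filter_de()].
#' @return List with `kept` and `removed` (both sorted character vectors);
#'   the two partition `candidates`.
#' @export
remove_control_fp <- function(candidates, oa_hc_records, min_abs_lfc = 1.0,
                              max_p = 0.05, use_q = FALSE) {
  stopifnot(is.character(candidates) || length(candidates) == 0L)
  if (nrow(oa_hc_records) &&
      !all(oa_hc_records$comparison == "OA_vs_HC")) {
    stop("expected records from the OA_vs_HC comparison only", call. = FALSE)
  }
  de_oa_hc <- filter_de(oa_hc_records, min_abs_lfc, max_p, use_q)$gene
  removed <- sort(intersect(candidates, de_oa_hc))
  list(kept = sort(setdiff(candidates, removed)), removed = removed)
}

# Shared walk over per-series evidence: per gene, the logFC observed in each
# series it was measured in.
.gene_evidence <- function(per_series) {
  stopifnot(is.list(per_series), length(per_series) >= 1L)
  ev <- do.call(rbind, lapply(names(per_series), function(sid) {
    df <- per_series[[sid]]
    data.frame(gene = df$gene, series = rep(sid, nrow(df)),
               logFC = df$logFC, stringsAsFactors = FALSE)
  }))
  split(ev, ev$gene)
}

#' Strict multi-series consistency filter
#'
#' Retains genes measured in every series whose log2 fold change has the
#' same sign in all series and magnitude `>= min_abs_lfc` in all series
#' (the "differential expression in each comparison group" rule). p-values
#' are deliberately not enforced here; significance filtering belongs to the
#' upstream per-series [filter_de()] stage.
#'
#' @param per_series Named list (one element per series) of data.frames with
#'   columns `gene` and `logFC`, all from the same comparison.
#' @param min_abs_lfc Fold-change threshold (inclusive); default 1.
#' @return Data.frame with columns `gene` and `sign` (+1/-1), sorted by
#'   gene.
#' @export
strict_consistency <- function(per_series, min_abs_lfc = 1.0) {
  if (length(per_series) < 2L) {
    stop("strict consistency needs >= 2 series", call. = FALSE)
  }
  by_gene <- .gene_evidence(per_series)
  n_series <- length(per_series)
  keep <- vapply(by_gene, function(ev) {
    nrow(ev) == n_series &&
      all(abs(ev$logFC) >= min_abs_lfc) &&
      length(unique(sign(ev$logFC))) == 1L
  }, logical(1))
  genes <- names(by_gene)[keep]
  out <- data.frame(
    gene = genes,
    sign = vapply(by_gene[genes], function(ev) sign(ev$logFC[[1L]]),
                  numeric(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE,
    row.names = NULL
  )[order(genes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relaxed multi-series consistency filter
#'
#' Retains genes whose log2 fold change reaches `min_abs_lfc` in at least
#' one series, provided the series that reach the threshold agree in sign
#' (the "differential expression in at least one round of comparison" rule).
#' Genes missing from some series may still qualify through the series in
#' which they were measured. The strict-tier output is always a subset of
#' the relaxed-tier output.
#'
#' @inheritParams strict_consistency
#' @return Data.frame with columns `gene` and `sign`, sorted by gene; the
#'   sign is that of the qualifying series.
#' @export
relaxed_consistency <- function(per_series, min_abs_lfc = 1.0) {
  by_gene <- .gene_evidence(per_series)
  res <- lapply(by_gene, function(ev) {
    qual <- ev$logFC[abs(ev$logFC) >= min_abs_lfc]
    if (!length(qual)) return(NULL)
    s <- unique(sign(qual))
    if (length(s) != 1L) return(NULL)
    s
  })
  keep <- !vapply(res, is.null, logical(1))
  genes <- names(by_gene)[keep]
  out <- data.frame(
    gene = genes,
    sign = unlist(res[keep], use.names = FALSE),
    stringsAsFactors = FALSE,
    row.names = NULL
  )[order(genes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.dir_to_sign <- function(direction) ifelse(direction == "up", 1, -1)

#' Call anticorrelated (miRNA, gene) pairs
#'
#' A candidate gene is paired with each of its predicted miRNAs whose
#' curated direction in RA opposes the gene's expression sign (miRNA up with
#' gene down, or miRNA down with gene up) — the operational meaning of a
#' negatively correlated miRNA/mRNA pair when no paired per-sample miRNA
#' measurements exist. Discordant miRNAs are dropped edge-wise; genes left
#' with no concordant miRNA are dropped.
#'
#' @param genes_with_sign Data.frame with columns `gene` and `sign` (from a
#'   consistency filter).
#' @param mirna_table Curated miRNA table (columns `mirna_id`,
#'   `previous_ids`, `direction`), e.g.
#'   `load_fixture_table("mirna_table")`.
#' @param gene_to_mirnas Named list `gene -> character vector of miRNA
#'   labels` (from [invert_targets()] or a fixture's `mirnas` column).
#' @return Data.frame with one row per retained gene: `gene`, `mirnas`
#'   (semicolon-joined, sorted), `sign`, `anticorrelated` (all `TRUE`),
#'   sorted by gene.
#' @export
anticorrelated_pairs <- function(genes_with_sign, mirna_table,
                                 gene_to_mirnas) {
  dirs <- mirna_directions(mirna_table)
  rows <- lapply(seq_len(nrow(genes_with_sign)), function(i) {
    gene <- genes_with_sign$gene[[i]]
    gsign <- genes_with_sign$sign[[i]]
    mirnas <- gene_to_mirnas[[gene]]
    if (is.null(mirnas)) {
      stop("gene has no candidate miRNA in the map: ", gene, call. = FALSE)
    }
    unknown <- setdiff(mirnas, names(dirs))
    if (length(unknown)) {
      stop("miRNA(s) absent from the curated table: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    concordant <- mirnas[gsign == -.dir_to_sign(dirs[mirnas])]
    if (!length(concordant)) return(NULL)
    data.frame(gene = gene,
               mirnas = paste(sort(concordant), collapse = "; "),
               sign = gsign, anticorrelated = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), mirnas = character(0),
                      sign = numeric(0), anticorrelated = logical(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full candidate-selection cascade
#'
#' Orchestrates the selection of anticorrelated miRNA/mRNA pair candidates
#' from per-series differential-expression tables:
#'
#' 1. restrict genes to consensus predicted targets of the curated miRNAs;
#' 2. per-series DE filtering ([filter_de()]); a gene stays a candidate if
#'    it passes in at least one series (when `enforce_p = FALSE` only the
#'    fold-change threshold is applied, the mode used with curated record
#'    tables whose significance filtering already happened upstream);
#' 3. control-vs-control false-positive removal when an `OA_vs_HC` table is
#'    supplied ([remove_control_fp()]);
#' 4. strict and relaxed multi-series consistency filters;
#' 5. anticorrelation pair calling against the curated miRNA directions.
#'
#' @param de_tables Named list (by series id) of [run_de()]-style data.frames
#'   for the RA-vs-control comparison of interest.
#' @param mirna_table Curated miRNA direction table.
#' @param consensus_map Named list `mirna_id -> genes` ([consensus_all()]).
#' @param oa_hc_records Optional `OA_vs_HC` [run_de()] table for
#'   false-positive removal; `NULL` to skip.
#' @param min_abs_lfc,max_p,use_q Thresholds for [filter_de()] and the
#'   consistency filters.
#' @param enforce_p Apply the p/q threshold during candidate filtering
#'   (`TRUE` when running from raw expression matrices).
#' @return List with `strict_pairs`, `relaxed_pairs` (data.frames as from
#'   [anticorrelated_pairs()], with a `tier` column) and `fp_removed`
#'   (character vector).
#' @export
select_candidates <- function(de_tables, mirna_table, consensus_map,
                              oa_hc_records = NULL, min_abs_lfc = 1.0,
                              max_p = 0.05, use_q = FALSE,
                              enforce_p = TRUE) {
  stopifnot(is.list(de_tables), length(de_tables) >= 1L,
            !is.null(names(de_tables)))
  gene_to_mirnas <- invert_targets(consensus_map)
  target_genes <- names(gene_to_mirnas)

  restricted <- lapply(de_tables, function(df) {
    df[df$gene %in% target_genes, , drop = FALSE]
  })

  passing <- lapply(restricted, function(df) {
    if (enforce_p) filter_de(df, min_abs_lfc, max_p, use_q)$gene
    else df$gene[abs(df$logFC) >= min_abs_lfc]
  })
  candidates <- sort(unique(unlist(passing, use.names = FALSE)))

  fp_removed <- character(0)
  if (!is.null(oa_hc_records)) {
    fp <- remove_control_fp(candidates, oa_hc_records, min_abs_lfc, max_p,
                            use_q)
    candidates <- fp$kept
    fp_removed <- fp$removed
  }

  surviving <- lapply(restricted, function(df) {
    df[df$gene %in% candidates, , drop = FALSE]
  })

  strict <- if (length(surviving) >= 2L) {
    strict_consistency(surviving, min_abs_lfc)
  } else {
    # single-series runs: the strict rule degenerates to the relaxed rule
    relaxed_consistency(surviving, min_abs_lfc)
  }
  relaxed <- relaxed_consistency(surviving, min_abs_lfc)

  strict_pairs <- anticorrelated_pairs(strict, mirna_table, gene_to_mirnas)
  relaxed_pairs <- anticorrelated_pairs(relaxed, mirna_table, gene_to_mirnas)
  if (nrow(strict_pairs)) strict_pairs$tier <- "strict"
  else strict_pairs$tier <- character(0)
  if (nrow(relaxed_pairs)) relaxed_pairs$tier <- "relaxed"
  else relaxed_pairs$tier <- character(0)

  list(strict_pairs = strict_pairs, relaxed_pairs = relaxed_pairs,
       fp_removed = fp_removed)
}

#' Per-series evidence tables from a curated record table
#'
#' Reshapes a bundled candidate table (wide: `logFC_<series>` / `p_<series>`
#' column pairs) into the named list of long per-series tables the
#' consistency filters consume, and its `mirnas` column into the gene ->
#' miRNA map for [anticorrelated_pairs()].
#'
#' @param fixture Data.frame from [load_fixture_table()] with a `gene`
#'   column, a `mirnas` column, and `logFC_*`/`p_*` column pairs.
#' @return List with `per_series` (named list of data.frames with `gene`,
#'   `logFC`, `p`) and `gene_to_mirnas` (named list).
#' @export
fixture_evidence <- function(fixture) {
  lfc_cols <- grep("^logFC_", names(fixture), value = TRUE)
  if (!length(lfc_cols)) stop("no logFC_* columns found", call. = FALSE)
  series_ids <- sub("^logFC_", "", lfc_cols)
  per_series <- stats::setNames(lapply(series_ids, function(sid) {
    data.frame(gene = fixture$gene,
               logFC = fixture[[paste0("logFC_", sid)]],
               p = fixture[[paste0("p_", sid)]],
               stringsAsFactors = FALSE)
  }), series_ids)
  g2m <- stats::setNames(split_mirnas(fixture$mirnas), fixture$gene)
  list(per_series = per_series, gene_to_mirnas = g2m)
}
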