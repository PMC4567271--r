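#' Log2 fold change between two FPKM values
#'
#' Computes `log2((case + pseudocount) / (control + pseudocount))`, the
#' expression ratio reported for RNA-seq comparisons. With the default
#' pseudocount of 0 this reproduces published FPKM ratios exactly; a small
#' positive pseudocount stabilises low-coverage genes.
#'
#' @param fpkm_control,fpkm_case Non-negative FPKM values (vectorised).
#' @param pseudocount Non-negative value added to both terms; default 0.
#' @return Numeric log2 fold change(s), case over control.
#' @export
fpkm_log_ratio <- function(fpkm_control, fpkm_case, pseudocount = 0) {
  stopifnot(is.numeric(fpkm_control), is.numeric(fpkm_case),
            length(pseudocount) == 1L, pseudocount >= 0)
  if (any(fpkm_control < 0) || any(fpkm_case < 0)) {
    stop("FPKM values must be >= 0", call. = FALSE)
  }
  if (pseudocount == 0 && any(fpkm_control == 0 & fpkm_case == 0)) {
    stop("log fold change undefined: both FPKM values are 0 and pseudocount is 0",
         call. = FALSE)
  }
  log2((fpkm_case + pseudocount) / (fpkm_control + pseudocount))
}

#' Group-level log2 fold change for one gene
#'
#' Microarray-kind series (values already on the log2 scale) use the
#' difference of group means; RNA-seq-kind series use the log2 ratio of group
#' mean FPKM via [fpkm_log_ratio()].
#'
#' @param series An [expression_series()] object.
#' @param gene Gene identifier (row name).
#' @param case_group,control_group Group labels present in the series.
#' @param pseudocount Passed to [fpkm_log_ratio()] for RNA-seq series.
#' @return Log2 fold change, case over control.
#' @export
group_log_fold_change <- function(series, gene, case_group, control_group,
                                  pseudocount = 0) {
  stopifnot(inherits(series, "ExpressionSeries"))
  if (!gene %in% rownames(series$values)) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  case_idx <- which(series$groups == case_group)
  ctrl_idx <- which(series$groups == control_group)
  if (!length(case_idx) || !length(ctrl_idx)) {
    stop("empty group: ",
         if (!length(case_idx)) case_group else control_group, call. = FALSE)
  }
  row <- series$values[gene, ]
  if (series$kind == "microarray") {
    mean(row[case_idx]) - mean(row[ctrl_idx])
  } else {
    fpkm_log_ratio(mean(row[ctrl_idx]), mean(row[case_idx]), pseudocount)
  }
}

#' Welch's unequal-variance two-sample t test
#'
#' Two-sided Welch t test with Welch-Satterthwaite degrees of freedom, the
#' generic calibrated test applied gene-wise in [run_de()]. Swapping the two
#' groups negates `t` and preserves `p`.
#'
#' @param values_case,values_control Numeric vectors, each of length >= 2.
#' @return List with elements `t`, `df` and `p`.
#' @export
welch_test <- function(values_case, values_control) {
  if (length(values_case) < 2L || length(values_control) < 2L) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  if (stats::var(values_case) == 0 && stats::var(values_control) == 0) {
    stop("degenerate input: zero variance in both groups", call. = FALSE)
  }
  fit <- stats::t.test(values_case, values_control, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Maps p-values to q-values controlling the false discovery rate:
#' `q_(i) = min_{j >= i} p_(j) * n / j` on the sorted values, mapped back to
#' input order. Monotone in p and never below the input p-value.
#'
#' @param p_values Numeric vector with all values in `[0, 1]`.
#' @return Numeric vector of q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values))
  if (length(p_values) && (any(p_values < 0) || any(p_values > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

.comparison_groups <- function(comparison) {
  switch(comparison,
    RA_vs_HC = c(case = "RA", control = "HC"),
    RA_vs_OA = c(case = "RA", control = "OA"),
    OA_vs_HC = c(case = "OA", control = "HC"),
    stop("unknown comparison '", comparison,
         "' (expected RA_vs_HC, RA_vs_OA or OA_vs_HC)", call. = FALSE)
  )
}

#' Two-group differential expression over a whole series
#'
#' For every gene: the group log2 fold change (case over control; see
#' [group_log_fold_change()]) and a two-sided Welch t test. Microarray series
#' are tested on their log2 intensities directly; RNA-seq series are tested
#' on `log2(FPKM + 1)` to keep the test stable for low-coverage genes, while
#' the reported fold change stays the plain FPKM ratio. q-values are
#' Benjamini-Hochberg over all genes in the series.
#'
#' @param series An [expression_series()] object.
#' @param comparison One of `"RA_vs_HC"`, `"RA_vs_OA"`, `"OA_vs_HC"` (the
#'   case group is listed first).
#' @param pseudocount Pseudocount for the RNA-seq fold-change ratio.
#' @return Data.frame with one row per gene: `gene`, `series_id`,
#'   `comparison`, `logFC`, `p`, `q`, `mean_case`, `mean_control` (log2 scale
#'   for microarray, FPKM for RNA-seq).
#' @export
run_de <- function(series, comparison, pseudocount = 0) {
  stopifnot(inherits(series, "ExpressionSeries"))
  grp <- .comparison_groups(comparison)
  case_idx <- which(series$groups == grp[["case"]])
  ctrl_idx <- which(series$groups == grp[["control"]])
  if (!length(case_idx)) {
    stop("group absent from series: ", grp[["case"]], call. = FALSE)
  }
  if (!length(ctrl_idx)) {
    stop("group absent from series: ", grp[["control"]], call. = FALSE)
  }
  vals <- series$values
  test_vals <- if (series$kind == "rnaseq") log2(vals + 1) else vals
  mean_case <- rowMeans(vals[, case_idx, drop = FALSE])
  mean_ctrl <- rowMeans(vals[, ctrl_idx, drop = FALSE])
  logfc <- if (series$kind == "microarray") {
    mean_case - mean_ctrl
  } else {
    fpkm_log_ratio(mean_ctrl, mean_case, pseudocount)
  }
  p <- vapply(seq_len(nrow(vals)), function(i) {
    welch_test(test_vals[i, case_idx], test_vals[i, ctrl_idx])$p
  }, numeric(1))
  data.frame(
    gene = rownames(vals),
    series_id = series$series_id,
    comparison = comparison,
    logFC = unname(logfc),
    p = p,
    q = bh_adjust(p),
    mean_case = unname(mean_case),
    mean_control = unname(mean_ctrl),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Filter differential-expression records on effect size and significance
#'
#' Keeps records with `|logFC| >= min_abs_lfc` (inclusive: a 2-fold change is
#' `|logFC| >= 1`) and p (or BH q, when `use_q = TRUE`) strictly below
#' `max_p`.
#'
#' @param records Data.frame as returned by [run_de()] (needs columns
#'   `logFC` and `p`, and `q` when `use_q = TRUE`).
#' @param min_abs_lfc Minimum absolute log2 fold change; default 1.
#' @param max_p Significance cutoff (strict inequality); default 0.05.
#' @param use_q Apply the cutoff to BH q-values instead of raw p.
#' @return The subset of `records` passing both thresholds.
#' @export
filter_de <- function(records, min_abs_lfc = 1.0, max_p = 0.05,
                      use_q = FALSE) {
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(records)
  sig <- if (use_q) records$q else records$p
  records[abs(records$logFC) >= min_abs_lfc & sig < max_p, , drop = FALSE]
}

#' Write / read differential-expression tables
#'
#' Tab-separated with a header; numeric columns written with 3 decimals.
#'
#' @param records Data.frame from [run_de()].
#' @param path File path.
#' @return `write_de_table` invisibly returns `path`; `read_de_table`
#'   returns the data.frame.
#' @export
write_de_table <- function(records, path) {
  out <- records
  for (col in c("logFC", "p", "q", "mean_case", "mean_control")) {
    if (col %in% names(out)) out[[col]] <- sprintf("%.3f", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
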