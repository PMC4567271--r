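#' Hypergeometric gene-set enrichment
#'
#' Over-representation analysis of a gene list against an annotation
#' collection: for each term with at least one list gene, the upper-tail
#' hypergeometric probability `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`, where `N` is the universe size, `K` the
#' term size within the universe, `n` the list size within the universe and
#' `k` the list/term overlap. q-values are Benjamini-Hochberg across the
#' tested terms only (terms with `k = 0` are not tested and do not enter the
#' adjustment). The universe is an explicit argument: enrichment p-values
#' are only meaningful relative to a stated background.
#'
#' @param gene_list Non-empty character vector of gene symbols; genes
#'   outside the universe are dropped with a warning.
#' @param collection Named list `term_id -> genes` with a `descriptions`
#'   attribute, as from [read_gmt()].
#' @param universe Non-empty character vector of background gene symbols.
#' @return Data.frame sorted by ascending `p` (ties broken by `term_id`)
#'   with columns `term_id`, `description`, `k`, `K`, `n`, `N`, `p`, `q`.
#' @export
enrichment <- function(gene_list, collection, universe) {
  if (!length(gene_list)) stop("empty gene list", call. = FALSE)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    warning("dropping ", length(outside),
            " gene(s) outside the universe: ",
            paste(utils::head(outside, 5L), collapse = ", "),
            if (length(outside) > 5L) ", ..." else "", call. = FALSE)
    gene_list <- intersect(gene_list, universe)
  }
  if (!length(gene_list)) stop("no gene in the list lies in the universe",
                               call. = FALSE)
  N <- length(universe)
  n <- length(gene_list)
  desc <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(term) {
    term_genes <- intersect(collection[[term]], universe)
    K <- length(term_genes)
    k <- length(intersect(term_genes, gene_list))
    if (k == 0L) return(NULL)
    data.frame(
      term_id = term,
      description = if (!is.null(desc) && term %in% names(desc))
        desc[[term]] else term,
      k = k, K = K, n = n, N = N,
      p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
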