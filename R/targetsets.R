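#' Consensus miRNA target set from two prediction sources
#'
#' The consensus rule intersects the target predictions of two independent
#' sources to cut prediction false positives; only genes called by both are
#' retained. When the first source lacks a miRNA altogether (older
#' prediction catalogues track fewer mature miRNAs), the second, more
#' complete source is used alone and the entry is flagged as a fallback.
#'
#' @param preds Target predictions: a list with named-list elements
#'   `source_a` and `source_b` mapping `mirna_id` to a character vector of
#'   gene symbols (see [gen_target_dbs()] or [read_gmt()]), and optionally
#'   `universe`.
#' @param mirna_id miRNA to look up; must be present in `source_b`.
#' @return List with `genes` (sorted character vector) and `used_fallback`
#'   (logical flag).
#' @export
consensus <- function(preds, mirna_id) {
  in_a <- mirna_id %in% names(preds$source_a)
  in_b <- mirna_id %in% names(preds$source_b)
  if (!in_a && !in_b) {
    stop("miRNA absent from both prediction sources: ", mirna_id,
         call. = FALSE)
  }
  if (!in_b) {
    stop("miRNA absent from source_b (required as the complete source): ",
         mirna_id, call. = FALSE)
  }
  if (!in_a) {
    list(genes = sort(unique(preds$source_b[[mirna_id]])),
         used_fallback = TRUE)
  } else {
    list(genes = sort(intersect(preds$source_a[[mirna_id]],
                                preds$source_b[[mirna_id]])),
         used_fallback = FALSE)
  }
}

#' Consensus sets for every miRNA in the second source
#'
#' @inheritParams consensus
#' @return Named list `mirna_id -> character vector of genes`, with a
#'   logical `used_fallback` attribute (named by miRNA).
#' @export
consensus_all <- function(preds) {
  ids <- names(preds$source_b)
  out <- vector("list", length(ids))
  fb <- logical(length(ids))
  for (i in seq_along(ids)) {
    res <- consensus(preds, ids[[i]])
    out[[i]] <- res$genes
    fb[[i]] <- res$used_fallback
  }
  names(out) <- ids
  structure(out, used_fallback = stats::setNames(fb, ids))
}

#' Significance of the overlap between two gene sets
#'
#' One-sided enrichment test of the overlap `k` between a set of size `m_a`
#' and a set of size `m_b` drawn from a universe of `N` genes:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N, m_a, m_b)` (equivalently the
#' one-sided Fisher exact test on the 2x2 table). The odds ratio is the
#' cross-product ratio of `[[k, m_a-k], [m_b-k, N-m_a-m_b+k]]`.
#'
#' @param m_a,m_b Sizes of the two sets.
#' @param k Observed overlap.
#' @param N Universe size.
#' @return List with `k`, `m_a`, `m_b`, `N`, `p` and `odds_ratio`.
#' @export
overlap_significance <- function(m_a, m_b, k, N) {
  stopifnot(length(m_a) == 1L, length(m_b) == 1L, length(k) == 1L,
            length(N) == 1L)
  if (m_a > N || m_b > N) stop("set sizes cannot exceed N", call. = FALSE)
  if (k > min(m_a, m_b)) {
    stop("overlap k cannot exceed min(m_a, m_b)", call. = FALSE)
  }
  if (k < max(0, m_a + m_b - N)) {
    stop("overlap k below the feasible minimum max(0, m_a + m_b - N)",
         call. = FALSE)
  }
  p <- stats::phyper(k - 1, m_a, N - m_a, m_b, lower.tail = FALSE)
  or <- (k * (N - m_a - m_b + k)) / ((m_a - k) * (m_b - k))
  list(k = k, m_a = m_a, m_b = m_b, N = N, p = p, odds_ratio = or)
}

#' Invert a consensus map to gene -> miRNAs
#'
#' @param consensus_map Named list `mirna_id -> character vector of genes`
#'   (e.g. from [consensus_all()]).
#' @return Named list `gene -> sorted character vector of mirna_ids`; genes
#'   with no miRNA do not appear.
#' @export
invert_targets <- function(consensus_map) {
  if (!length(consensus_map)) return(stats::setNames(list(), character(0)))
  edges <- data.frame(
    mirna = rep(names(consensus_map), lengths(consensus_map)),
    gene = unlist(consensus_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (!nrow(edges)) return(stats::setNames(list(), character(0)))
  lapply(split(edges$mirna, edges$gene), function(m) sort(unique(m)))
}
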