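#' Build the bipartite miRNA-gene regulatory network
#'
#' One node per miRNA and per gene appearing in the pair table, one edge per
#' retained (miRNA, gene) pair. miRNA nodes carry their regulatory direction
#' and the display class `"blue"`; gene nodes carry their expression sign
#' and `"red"` (up) or `"green"` (down). The graph is strictly bipartite
#' and every edge must satisfy the anticorrelation identity
#' `sign(gene) == -direction(miRNA)`; a violation is a hard error.
#'
#' @param pairs Data.frame from [anticorrelated_pairs()] /
#'   [select_candidates()] (columns `gene`, `mirnas`, `sign`; optional
#'   `tier`).
#' @param provenance Optional label recording tier and source-data kind.
#' @return An object of class `RegulatoryNetwork`: list with data.frames
#'   `mirna_nodes` (`id`, `direction`, `color_class`), `gene_nodes` (`id`,
#'   `sign`, `color_class`), `edges` (`mirna`, `gene`) and `provenance`.
#' @export
build_network <- function(pairs, provenance = NA_character_) {
  stopifnot(is.data.frame(pairs))
  if (!nrow(pairs)) {
    return(structure(list(
      mirna_nodes = data.frame(id = character(0), direction = character(0),
                               color_class = character(0),
                               stringsAsFactors = FALSE),
      gene_nodes = data.frame(id = character(0), sign = numeric(0),
                              color_class = character(0),
                              stringsAsFactors = FALSE),
      edges = data.frame(mirna = character(0), gene = character(0),
                         stringsAsFactors = FALSE),
      provenance = provenance
    ), class = "RegulatoryNetwork"))
  }
  mirna_lists <- split_mirnas(pairs$mirnas)
  edges <- data.frame(
    mirna = unlist(mirna_lists, use.names = FALSE),
    gene = rep(pairs$gene, lengths(mirna_lists)),
    stringsAsFactors = FALSE
  )
  gene_sign <- stats::setNames(pairs$sign, pairs$gene)
  if (length(intersect(edges$mirna, edges$gene))) {
    stop("network is not bipartite: identifier(s) used as both miRNA and gene: ",
         paste(intersect(edges$mirna, edges$gene), collapse = ", "),
         call. = FALSE)
  }
  # each edge encodes anticorrelation, so the miRNA direction is the
  # opposite of its target genes' shared sign; conflicting implied
  # directions mean the pair table violated the sign identity
  implied <- tapply(-gene_sign[edges$gene], edges$mirna,
                    function(s) unique(s))
  bad <- names(implied)[lengths(implied) != 1L]
  if (length(bad)) {
    stop("anticorrelation identity violated for miRNA(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mirna_ids <- sort(unique(edges$mirna))
  dir_sign <- vapply(implied[mirna_ids], identity, numeric(1))
  gene_ids <- sort(unique(edges$gene))
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    mirna_nodes = data.frame(
      id = mirna_ids,
      direction = ifelse(dir_sign > 0, "up", "down"),
      color_class = "blue",
      stringsAsFactors = FALSE, row.names = NULL
    ),
    gene_nodes = data.frame(
      id = gene_ids,
      sign = unname(gene_sign[gene_ids]),
      color_class = ifelse(gene_sign[gene_ids] > 0, "red", "green"),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    edges = edges,
    provenance = provenance
  ), class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat(sprintf("RegulatoryNetwork: %d miRNA node(s), %d gene node(s), %d edge(s)\n",
              nrow(x$mirna_nodes), nrow(x$gene_nodes), nrow(x$edges)))
  invisible(x)
}

#' Serialise a regulatory network as SIF
#'
#' One line per edge, `mirna targets gene`, emitted in lexicographic order
#' so output is byte-stable across runs.
#'
#' @param net A [build_network()] object.
#' @return Character scalar (lines joined by newline; empty string for an
#'   empty network).
#' @export
to_sif <- function(net) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  if (!nrow(net$edges)) return("")
  paste(sprintf("%s targets %s", net$edges$mirna, net$edges$gene),
        collapse = "\n")
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Serialise a regulatory network as GraphML
#'
#' Nodes carry `node_type` (`mirna`/`gene`), `direction` or `sign`, and
#' `color_class` attributes; edges are directed miRNA -> gene. Emission
#' order is lexicographic for byte-stable output.
#'
#' @param net A [build_network()] object.
#' @return Character scalar containing the GraphML document.
#' @export
to_graphml <- function(net) {
  stopifnot(inherits(net, "RegulatoryNetwork"))
  header <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="node" attr.name="node_type" attr.type="string"/>',
    '  <key id="d1" for="node" attr.name="direction" attr.type="string"/>',
    '  <key id="d2" for="node" attr.name="sign" attr.type="double"/>',
    '  <key id="d3" for="node" attr.name="color_class" attr.type="string"/>',
    '  <graph id="G" edgedefault="directed">'
  )
  mirna_xml <- vapply(seq_len(nrow(net$mirna_nodes)), function(i) {
    n <- net$mirna_nodes[i, ]
    sprintf(paste0('    <node id="%s">\n',
                   '      <data key="d0">mirna</data>\n',
                   '      <data key="d1">%s</data>\n',
                   '      <data key="d3">%s</data>\n',
                   '    </node>'),
            .xml_escape(n$id), n$direction, n$color_class)
  }, character(1))
  gene_xml <- vapply(seq_len(nrow(net$gene_nodes)), function(i) {
    n <- net$gene_nodes[i, ]
    sprintf(paste0('    <node id="%s">\n',
                   '      <data key="d0">gene</data>\n',
                   '      <data key="d2">%s</data>\n',
                   '      <data key="d3">%s</data>\n',
                   '    </node>'),
            .xml_escape(n$id), format(n$sign), n$color_class)
  }, character(1))
  edge_xml <- vapply(seq_len(nrow(net$edges)), function(i) {
    e <- net$edges[i, ]
    sprintf('    <edge source="%s" target="%s"/>',
            .xml_escape(e$mirna), .xml_escape(e$gene))
  }, character(1))
  paste(c(header, mirna_xml, gene_xml, edge_xml,
          "  </graph>", "</graphml>"), collapse = "\n")
}

#' Write SIF / GraphML network files
#'
#' @param net A [build_network()] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(net, path) {
  writeLines(to_sif(net), path)
  invisible(path)
}

#' @rdname write_sif
#' @export
write_graphml <- function(net, path) {
  writeLines(to_graphml(net), path)
  invisible(path)
}
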