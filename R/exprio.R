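#' Construct an expression series
#'
#' An `ExpressionSeries` bundles one study's gene-by-sample expression matrix
#' with its sample group labels and a kind tag. Microarray-kind series carry
#' log2 intensities; RNA-seq-kind series carry FPKM (fragments per kilobase of
#' exon per million mapped fragments), which must be non-negative.
#'
#' @param series_id Single string identifying the series (e.g. a GEO
#'   accession).
#' @param kind Either `"microarray"` or `"rnaseq"`.
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @param groups Named character vector mapping every sample (column name) to
#'   a group in `RA`, `OA`, `HC`.
#' @return An object of class `ExpressionSeries`: a list with elements
#'   `series_id`, `kind`, `values` and `groups`.
#' @export
expression_series <- function(series_id, kind, values, groups) {
  stopifnot(is.character(series_id), length(series_id) == 1L)
  kind <- match.arg(kind, c("microarray", "rnaseq"))
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    stop("'values' must have gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  if (kind == "rnaseq" && any(values < 0)) {
    stop("FPKM values must be >= 0", call. = FALSE)
  }
  missing <- setdiff(samples, names(groups))
  if (length(missing)) {
    stop("samples missing a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- groups[samples]
  bad <- setdiff(unique(groups), c("RA", "OA", "HC"))
  if (length(bad)) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected RA, OA or HC)", call. = FALSE)
  }
  structure(
    list(series_id = series_id, kind = kind, values = values, groups = groups),
    class = "ExpressionSeries"
  )
}

#' @export
print.ExpressionSeries <- function(x, ...) {
  cat(sprintf(
    "ExpressionSeries '%s' (%s): %d genes x %d samples [%s]\n",
    x$series_id, x$kind, nrow(x$values), ncol(x$values),
    paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Read an expression matrix with sample metadata
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and gene identifiers in the first column. The metadata file has two
#' tab-separated columns, `sample` and `group`, with a header.
#'
#' @param path Path to the expression matrix file.
#' @param kind `"microarray"` or `"rnaseq"`.
#' @param metadata_path Path to the two-column sample/group file.
#' @param series_id Series identifier; defaults to the matrix file name
#'   without extension.
#' @return An [expression_series()] object.
#' @export
read_expression <- function(path, kind, metadata_path, series_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!file.exists(metadata_path)) {
    stop("no such file: ", metadata_path, call. = FALSE)
  }
  if (is.null(series_id)) {
    series_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) {
    stop(path, ": expected gene column plus at least one sample column",
         call. = FALSE)
  }
  genes <- trimws(tab[[1L]])
  num <- as.data.frame(lapply(tab[-1L], function(col) {
    suppressWarnings(as.numeric(col))
  }))
  bad_cell <- which(is.na(as.matrix(num)) , arr.ind = TRUE)
  if (nrow(bad_cell)) {
    i <- bad_cell[1L, 1L]; j <- bad_cell[1L, 2L]
    stop(sprintf("%s: non-numeric value '%s' at line %d (gene %s, sample %s)",
                 path, tab[i, j + 1L], i + 1L, genes[i],
                 colnames(tab)[j + 1L]),
         call. = FALSE)
  }
  values <- as.matrix(num)
  rownames(values) <- genes
  colnames(values) <- colnames(tab)[-1L]

  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            colClasses = "character")
  if (!all(c("sample", "group") %in% colnames(meta))) {
    stop(metadata_path, ": expected columns 'sample' and 'group'",
         call. = FALSE)
  }
  groups <- stats::setNames(trimws(meta$group), trimws(meta$sample))
  expression_series(series_id, kind, values, groups)
}

#' Write an expression series to disk
#'
#' Writes the matrix (values formatted with 3 decimal places) and the
#' two-column sample metadata in the layout [read_expression()] consumes.
#'
#' @param series An [expression_series()] object.
#' @param path Output path for the matrix.
#' @param metadata_path Output path for the sample/group table.
#' @return Invisibly, `series`.
#' @export
write_expression <- function(series, path, metadata_path) {
  stopifnot(inherits(series, "ExpressionSeries"))
  vals <- series$values
  out <- data.frame(gene = rownames(vals),
                    apply(vals, 2L, function(col) sprintf("%.3f", col)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(out) <- c("gene", colnames(vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample = names(series$groups),
                     group = unname(series$groups))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(series)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set dialect: one set per line, fields
#' `term_id <tab> description <tab> gene1 <tab> gene2 ...`. The same carrier
#' is used for per-miRNA target prediction exports and for annotation
#' collections. Duplicate genes within a line are collapsed; gene order is
#' not meaningful.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (the gene sets), with a
#'   `descriptions` attribute mapping term id to its description.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning(path, ": empty GMT file", call. = FALSE)
    return(structure(list(), descriptions = character(0)))
  }
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  desc <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    if (length(fields) < 3L) {
      stop(sprintf("%s: line %d has %d field(s); GMT needs term, description and >=1 gene",
                   path, i, length(fields)), call. = FALSE)
    }
    ids[[i]] <- fields[[1L]]
    desc[[i]] <- fields[[2L]]
    genes <- fields[-(1:2)]
    sets[[i]] <- unique(genes[nzchar(genes)])
  }
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- ids
  structure(sets, descriptions = stats::setNames(desc, ids))
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors; an optional `descriptions`
#'   attribute (named character vector) supplies the second column, which
#'   otherwise repeats the term id.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else id
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.fixture_files <- c(
  mirna_table       = "mirna_table.tsv",
  ra_hc_microarray  = "ra_hc_microarray.tsv",
  ra_oa_microarray  = "ra_oa_microarray.tsv",
  ra_hc_rnaseq      = "ra_hc_rnaseq.tsv"
)

#' Load a bundled curated record table
#'
#' Four curated tables ship with the package, transcribed from the published
#' RA synovial fibroblast integration study at the precision they were
#' printed (3 decimals):
#'
#' * `"mirna_table"` — the 14 literature-curated RASF-dysregulated miRNAs
#'   with their direction in RA (`up`/`down`), their legacy identifiers, and
#'   the per-source / consensus predicted target-set sizes (the first
#'   prediction source lacks miR-34a-3p, recorded as `NA`).
#' * `"ra_hc_microarray"` — 13 strict-tier candidate genes with per-series
#'   (GSE21959, GSE29746) log2 fold change and p for the RA vs HC comparison.
#' * `"ra_oa_microarray"` — 39 relaxed-tier candidate genes with per-series
#'   (GSE29746, GSE7669, GSE49604) log2 fold change and p for RA vs OA.
#' * `"ra_hc_rnaseq"` — 15 representative RNA-seq candidates with group mean
#'   FPKM, log2 fold change and p for RA vs HC.
#'
#' @param name One of `"mirna_table"`, `"ra_hc_microarray"`,
#'   `"ra_oa_microarray"`, `"ra_hc_rnaseq"`.
#' @return A data.frame; `mirnas` columns hold semicolon-joined miRNA labels.
#' @export
load_fixture_table <- function(name) {
  if (!name %in% names(.fixture_files)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(.fixture_files), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", .fixture_files[[name]], package = "mirpairs",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Split a semicolon-joined miRNA label field
#'
#' @param x Character vector like `"miR-19b; miR-30a"`.
#' @return List of character vectors.
#' @export
split_mirnas <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), trimws)
}

#' Resolve a miRNA label to its curated record
#'
#' Candidate tables cite miRNAs by legacy names (e.g. `miR-124`,
#' `miR-34a*`); the curated table indexes them by mature identifier with a
#' `previous_ids` field. Matching tries the canonical id first, then the
#' legacy aliases; matching is exact after whitespace trimming.
#'
#' @param mirna_table Data.frame as returned by
#'   `load_fixture_table("mirna_table")` (columns `mirna_id`,
#'   `previous_ids`, `direction`).
#' @param labels Character vector of miRNA labels to resolve.
#' @return Character vector of canonical `mirna_id`s; error on any label
#'   that resolves to nothing.
#' @export
resolve_mirna <- function(mirna_table, labels) {
  alias <- list()
  for (i in seq_len(nrow(mirna_table))) {
    id <- mirna_table$mirna_id[[i]]
    alias[[id]] <- id
    prev <- trimws(strsplit(mirna_table$previous_ids[[i]], ";",
                            fixed = TRUE)[[1L]])
    for (p in prev[nzchar(prev)]) alias[[p]] <- id
  }
  labels <- trimws(labels)
  unknown <- setdiff(labels, names(alias))
  if (length(unknown)) {
    stop("miRNA label(s) not in the curated table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vapply(labels, function(l) alias[[l]], character(1), USE.NAMES = FALSE)
}

#' Direction of curated miRNAs in RA
#'
#' @inheritParams resolve_mirna
#' @return Named character vector `mirna_id -> "up"/"down"`, including one
#'   entry per legacy alias so lookups by either name succeed.
#' @export
mirna_directions <- function(mirna_table) {
  out <- stats::setNames(mirna_table$direction, mirna_table$mirna_id)
  for (i in seq_len(nrow(mirna_table))) {
    prev <- trimws(strsplit(mirna_table$previous_ids[[i]], ";",
                            fixed = TRUE)[[1L]])
    for (p in prev[nzchar(prev)]) out[[p]] <- mirna_table$direction[[i]]
  }
  out
}
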