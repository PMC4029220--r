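## Tabular input/output. All files are plain TSV, UTF-8, tab-separated,
## with a mandatory header row; lines starting with '#' are comments and
## skipped. Error messages carry 1-based file line numbers (counting the
## header and comment lines).

# Split a TSV file into header and data rows, tracking original line numbers.
.readTsv <- function(path, ncolExpected = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !startsWith(trimws(lines, "left"), "#") & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no header row in ", path, call. = FALSE)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (!is.null(ncolExpected) && length(header) != ncolExpected)
    stop(path, " line ", idx[1L], ": expected ", ncolExpected,
         " tab-separated columns, found ", length(header), call. = FALSE)
  rows <- fields[-1L]
  lineno <- idx[-1L]
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop(path, " line ", lineno[bad[1L]], ": expected ", length(header),
         " tab-separated columns, found ", lengths(rows)[bad[1L]],
         call. = FALSE)
  list(header = header, rows = rows, lineno = lineno)
}

.col <- function(tsv, j) vapply(tsv$rows, `[[`, character(1), j)

# Format numeric columns so values survive a write/read round trip exactly.
.fmtNum <- function(x) sprintf("%.17g", x)

.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], .fmtNum)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a ChIP binding table
#'
#' Parses a TSV of ChIP-derived TF-gene binding candidates with columns
#' `tf`, `gene`, `p_value` (the binding p-value under the hypothesis that
#' the TF binds the gene's promoter region). Row order is preserved.
#' Duplicate (tf, gene) rows are rejected: two binding p-values for the
#' same pair are ambiguous.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `tf`, `gene`, `p_binding`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("tf\tgene\tp_value", "TF1\tG1\t0.005", "TF1\tG2\t0.5"), f)
#' readBindingTable(f)
#' @export
readBindingTable <- function(path) {
  tsv <- .readTsv(path, ncolExpected = 3L)
  if (!identical(tsv$header, c("tf", "gene", "p_value")))
    stop(path, ": header must be 'tf<TAB>gene<TAB>p_value', found '",
         paste(tsv$header, collapse = "\\t"), "'", call. = FALSE)
  if (length(tsv$rows) == 0L)
    return(data.frame(tf = character(0), gene = character(0),
                      p_binding = numeric(0)))
  tf <- .col(tsv, 1L); gene <- .col(tsv, 2L); praw <- .col(tsv, 3L)
  p <- suppressWarnings(as.numeric(praw))
  bad <- which(is.na(p))
  if (length(bad))
    stop(path, " line ", tsv$lineno[bad[1L]], ": malformed p_value '",
         praw[bad[1L]], "'", call. = FALSE)
  bad <- which(p < 0 | p > 1)
  if (length(bad))
    stop(path, " line ", tsv$lineno[bad[1L]], ": p_value ", p[bad[1L]],
         " outside [0, 1]", call. = FALSE)
  bad <- which(!nzchar(tf) | !nzchar(gene))
  if (length(bad))
    stop(path, " line ", tsv$lineno[bad[1L]], ": empty tf or gene id",
         call. = FALSE)
  key <- paste(tf, gene, sep = "\r")
  bad <- which(duplicated(key))
  if (length(bad))
    stop(path, " line ", tsv$lineno[bad[1L]], ": duplicate pair (",
         tf[bad[1L]], ", ", gene[bad[1L]], ")", call. = FALSE)
  data.frame(tf = tf, gene = gene, p_binding = p)
}

#' Write a ChIP binding table
#'
#' Inverse of [readBindingTable()]; numeric values are written with enough
#' digits to round-trip exactly.
#'
#' @param bindings data.frame with columns `tf`, `gene`, `p_binding`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBindingTable <- function(bindings, path) {
  df <- data.frame(tf = bindings$tf, gene = bindings$gene,
                   p_value = bindings$p_binding)
  .writeTsv(df, path)
}

#' Read a regulation (or PPI) edge list
#'
#' Parses a two-column TSV of edges. Serves both TFKO regulation pairs
#' (directed, TF -> target) and physical protein-protein interaction pairs
#' (undirected by convention of the caller). Duplicate rows are collapsed
#' to one edge (evidence is idempotent); self-edges are retained with a
#' warning.
#'
#' @param path path to the TSV file. Any two-column header is accepted.
#' @return data.frame with columns `from`, `to`, duplicates removed.
#' @export
readEdgeList <- function(path) {
  tsv <- .readTsv(path, ncolExpected = 2L)
  if (length(tsv$rows) == 0L)
    return(data.frame(from = character(0), to = character(0)))
  from <- .col(tsv, 1L); to <- .col(tsv, 2L)
  bad <- which(!nzchar(from) | !nzchar(to))
  if (length(bad))
    stop(path, " line ", tsv$lineno[bad[1L]], ": empty node id",
         call. = FALSE)
  self <- which(from == to)
  if (length(self))
    warning(length(self), " self-edge(s) in ", path,
            " (first at line ", tsv$lineno[self[1L]], ")", call. = FALSE)
  dup <- duplicated(paste(from, to, sep = "\r"))
  data.frame(from = from[!dup], to = to[!dup])
}

#' Write an edge list
#'
#' @param edges data.frame with columns `from`, `to`.
#' @param path output path.
#' @param header character(2) column names to write.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(edges, path, header = c("from", "to")) {
  df <- data.frame(edges$from, edges$to)
  names(df) <- header
  .writeTsv(df, path)
}

#' Read a per-condition expression matrix
#'
#' First column `gene`, remaining columns one timepoint each (at least 3).
#' The condition identifier is the filename stem, attached as attribute
#' `condition`.
#'
#' @param path path to the TSV file.
#' @return numeric matrix, genes in rows (rownames), timepoints in columns.
#' @export
readExpressionMatrix <- function(path) {
  tsv <- .readTsv(path)
  if (tsv$header[1L] != "gene")
    stop(path, ": first column must be 'gene'", call. = FALSE)
  if (length(tsv$header) < 4L)
    stop(path, ": at least 3 timepoint columns required", call. = FALSE)
  genes <- .col(tsv, 1L)
  dup <- which(duplicated(genes))
  if (length(dup))
    stop(path, " line ", tsv$lineno[dup[1L]], ": duplicate gene id '",
         genes[dup[1L]], "'", call. = FALSE)
  ntp <- length(tsv$header) - 1L
  vals <- matrix(NA_real_, nrow = length(genes), ncol = ntp,
                 dimnames = list(genes, tsv$header[-1L]))
  for (j in seq_len(ntp)) {
    v <- suppressWarnings(as.numeric(.col(tsv, j + 1L)))
    bad <- which(is.na(v))
    if (length(bad))
      stop(path, " line ", tsv$lineno[bad[1L]], ": malformed expression value",
           call. = FALSE)
    vals[, j] <- v
  }
  attr(vals, "condition") <- sub("\\.[^.]*$", "", basename(path))
  vals
}

#' Write a per-condition expression matrix
#'
#' @param mat numeric matrix with gene rownames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeExpressionMatrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  .writeTsv(df, path)
}

#' Read a gene-to-term annotation table
#'
#' Columns `gene`, `term`, `namespace`; the namespace is restricted to the
#' three Gene Ontology branches: `process`, `function`, `component`.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene`, `term`, `namespace`.
#' @export
readAnnotationTable <- function(path) {
  tsv <- .readTsv(path, ncolExpected = 3L)
  if (length(tsv$rows) == 0L)
    return(data.frame(gene = character(0), term = character(0),
                      namespace = character(0)))
  ns <- .col(tsv, 3L)
  bad <- which(!ns %in% c("process", "function", "component"))
  if (length(bad))
    stop(path, " line ", tsv$lineno[bad[1L]], ": namespace '", ns[bad[1L]],
         "' not one of process/function/component", call. = FALSE)
  data.frame(gene = .col(tsv, 1L), term = .col(tsv, 2L), namespace = ns)
}

#' Write an annotation table
#'
#' @param annotations data.frame with columns `gene`, `term`, `namespace`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAnnotationTable <- function(annotations, path) {
  .writeTsv(annotations[c("gene", "term", "namespace")], path)
}

#' Write classified TF-gene pairs with their regulation cascades
#'
#' Emits one row per scored pair with the binding p-value, the evidence
#' case, the shortest regulation cascade (nodes joined by `"->"`; a direct
#' pair has cascade `"TF->gene"` and path length 1), the RCS, and the
#' functional verdict. Pairs without regulation evidence have `NA` cascade
#' and path length.
#'
#' @param results data.frame as returned by [scorePairs()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFunctionalPairs <- function(results, path) {
  df <- data.frame(
    tf = results$tf, gene = results$gene, p_binding = results$p_binding,
    evidence_case = results$evidence_case, cascade = results$cascade,
    path_length = results$observed_length, rcs = results$rcs,
    functional = results$functional)
  .writeTsv(df, path)
}

#' Read back a functional-pairs table written by [writeFunctionalPairs()]
#'
#' @param path path to the TSV file.
#' @return data.frame with the [scorePairs()] result columns that the
#'   writer emits.
#' @export
readFunctionalPairs <- function(path) {
  tsv <- .readTsv(path, ncolExpected = 8L)
  expectHeader <- c("tf", "gene", "p_binding", "evidence_case", "cascade",
                    "path_length", "rcs", "functional")
  if (!identical(tsv$header, expectHeader))
    stop(path, ": unexpected header", call. = FALSE)
  if (length(tsv$rows) == 0L)
    return(data.frame(tf = character(0), gene = character(0),
                      p_binding = numeric(0), evidence_case = character(0),
                      cascade = character(0), observed_length = integer(0),
                      rcs = numeric(0), functional = logical(0)))
  asNum <- function(x) suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  data.frame(
    tf = .col(tsv, 1L), gene = .col(tsv, 2L),
    p_binding = asNum(.col(tsv, 3L)),
    evidence_case = .col(tsv, 4L),
    cascade = ifelse(.col(tsv, 5L) == "NA", NA, .col(tsv, 5L)),
    observed_length = as.integer(asNum(.col(tsv, 6L))),
    rcs = asNum(.col(tsv, 7L)),
    functional = .col(tsv, 8L) == "TRUE")
}
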