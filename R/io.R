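## Tabular IO. All files are UTF-8, tab-separated, with a header row.

readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = "character", check.names = FALSE,
             comment.char = "", quote = "")
}

checkColumns <- function(tab, needed, path) {
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L)
    stop(sprintf("'%s': missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
}

## strict numeric conversion; reports 1-based data row numbers on failure
asNumericStrict <- function(x, column, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad) > 0L)
    stop(sprintf("'%s': non-numeric %s on row(s) %s", path, column,
                 paste(bad, collapse = ", ")), call. = FALSE)
  out
}

#' Read a differential-expression table
#'
#' Expects a TSV with header columns `gene_id`, `log2fc`, `fdr` (an optional
#' `call` column is kept if present). Rows with non-numeric values are
#' rejected with the offending row number; duplicate gene ids are an error.
#'
#' @param path path to a tab-separated file.
#' @return a [DEGTable-class].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tlog2fc\tfdr", "g1\t2.5\t0.01", "g2\t-3\t0.2"), tf)
#' readDEGTable(tf)
readDEGTable <- function(path) {
  tab <- readTsv(path)
  checkColumns(tab, c("gene_id", "log2fc", "fdr"), path)
  out <- data.frame(gene_id = tab$gene_id,
                    log2fc = asNumericStrict(tab$log2fc, "log2fc", path),
                    fdr = asNumericStrict(tab$fdr, "fdr", path),
                    stringsAsFactors = FALSE)
  if ("call" %in% names(tab)) out$call <- tab$call
  new("DEGTable", table = out)
}

#' Write a differential-expression table
#'
#' @param x a [DEGTable-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeDEGTable <- function(x, path) {
  stopifnot(is(x, "DEGTable"))
  writeTsv(x@table, path)
}

writeTsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style edge list into a PPINetwork
#'
#' Expects TSV columns `node_a`, `node_b`, `combined_score`. Self-loops are
#' dropped, edges below `scoreMin` are dropped, and duplicate unordered pairs
#' (STRING exports often list both orientations) are collapsed to a single
#' edge keeping the maximum score. Node identifiers are opaque and
#' case-sensitive. The resulting node set is exactly the endpoints of the
#' surviving edges.
#'
#' @param path path to a tab-separated file.
#' @param scoreMin minimum combined score to keep an edge (default 0).
#' @return a [PPINetwork-class]; empty after filtering gives an empty graph
#'   with a warning.
#' @export
readEdgeList <- function(path, scoreMin = 0) {
  tab <- readTsv(path)
  checkColumns(tab, c("node_a", "node_b", "combined_score"), path)
  score <- asNumericStrict(tab$combined_score, "combined_score", path)
  edgesToNetwork(tab$node_a, tab$node_b, score, scoreMin = scoreMin)
}

## shared constructor: canonicalize, drop loops, filter, dedupe keeping max
edgesToNetwork <- function(a, b, score, scoreMin = 0) {
  keep <- a != b & score >= scoreMin
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  if (length(lo) > 0L) {
    key <- paste0(lo, "\r", hi)
    ord <- order(key, -score)
    first <- !duplicated(key[ord])
    lo <- lo[ord][first]; hi <- hi[ord][first]; score <- score[ord][first]
  }
  if (length(lo) == 0L) {
    warning("no edges survive filtering; returning an empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    ed <- data.frame(from = lo, to = hi, combined_score = score,
                     stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  }
  new("PPINetwork", graph = g)
}

#' Build a PPINetwork from an in-memory edge table
#'
#' @param edges a `data.frame` with columns `node_a`, `node_b`,
#'   `combined_score`.
#' @param scoreMin minimum combined score to keep an edge.
#' @return a [PPINetwork-class].
#' @export
ppiNetwork <- function(edges, scoreMin = 0) {
  stopifnot(all(c("node_a", "node_b", "combined_score") %in% names(edges)))
  edgesToNetwork(as.character(edges$node_a), as.character(edges$node_b),
                 as.numeric(edges$combined_score), scoreMin = scoreMin)
}

#' Write a PPINetwork as an edge-list TSV
#'
#' @param x a [PPINetwork-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeEdgeList <- function(x, path) {
  stopifnot(is(x, "PPINetwork"))
  g <- x@graph
  if (igraph::ecount(g) == 0L) {
    tab <- data.frame(node_a = character(0), node_b = character(0),
                      combined_score = numeric(0))
  } else {
    ends <- igraph::as_edgelist(g)
    tab <- data.frame(node_a = ends[, 1], node_b = ends[, 2],
                      combined_score = igraph::E(g)$combined_score,
                      stringsAsFactors = FALSE)
  }
  writeTsv(tab, path)
}

#' Read a gene-to-GO annotation table
#'
#' Expects TSV columns `term_id`, `namespace` (BP/CC/MF), `gene_id`,
#' `term_background_count`, `population_background_count`.
#'
#' @param path path to a tab-separated file.
#' @return an [AnnotationSet-class].
#' @export
readAnnotations <- function(path) {
  tab <- readTsv(path)
  needed <- c("term_id", "namespace", "gene_id",
              "term_background_count", "population_background_count")
  checkColumns(tab, needed, path)
  ann <- data.frame(
    term_id = tab$term_id,
    namespace = tab$namespace,
    gene_id = tab$gene_id,
    term_background_count =
      as.integer(asNumericStrict(tab$term_background_count,
                                 "term_background_count", path)),
    population_background_count =
      as.integer(asNumericStrict(tab$population_background_count,
                                 "population_background_count", path)),
    stringsAsFactors = FALSE)
  new("AnnotationSet", annotations = ann)
}

#' @rdname readAnnotations
#' @param x an [AnnotationSet-class].
#' @param path output path.
#' @export
writeAnnotations <- function(x, path) {
  stopifnot(is(x, "AnnotationSet"))
  writeTsv(x@annotations, path)
}

#' Read a qPCR threshold-cycle table
#'
#' Expects TSV columns `gene_id`, `condition` (`test` or `calibrator`),
#' `replicate`, `ct_target`, `ct_reference`.
#'
#' @param path path to a tab-separated file.
#' @return a `data.frame`.
#' @export
readCtTable <- function(path) {
  tab <- readTsv(path)
  needed <- c("gene_id", "condition", "replicate", "ct_target", "ct_reference")
  checkColumns(tab, needed, path)
  bad <- setdiff(unique(tab$condition), c("test", "calibrator"))
  if (length(bad) > 0L)
    stop(sprintf("'%s': condition must be 'test' or 'calibrator' (got: %s)",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  data.frame(gene_id = tab$gene_id, condition = tab$condition,
             replicate = tab$replicate,
             ct_target = asNumericStrict(tab$ct_target, "ct_target", path),
             ct_reference = asNumericStrict(tab$ct_reference,
                                            "ct_reference", path),
             stringsAsFactors = FALSE)
}

#' Percentage of a whole, rounded half-up to two decimals
#'
#' The convention used for read-retention and length-class summaries:
#' `100 * part / whole` rounded half-up to 2 decimal places, so e.g.
#' 96403161 of 96411054 processed reads prints as 99.99.
#'
#' @param part non-negative integer count, at most `whole`.
#' @param whole positive integer count.
#' @return numeric percentage with two-decimal half-up rounding.
#' @export
#' @examples
#' proportionPercent(29175, 81952)  # 35.60
proportionPercent <- function(part, whole) {
  if (any(whole <= 0)) stop("whole must be > 0", call. = FALSE)
  if (any(part < 0)) stop("part must be >= 0", call. = FALSE)
  if (any(part > whole)) stop("part must not exceed whole", call. = FALSE)
  p <- 100 * part / whole
  ## half-up at the 2nd decimal; epsilon shields binary representation of .xx5
  floor(p * 100 + 0.5 + 1e-9) / 100
}
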