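#' Classify genes as up-/down-regulated or not significant
#'
#' A gene is called `up` when `log2fc >= lfcMin` and `fdr < fdrMax`, `down`
#' when `log2fc <= -lfcMin` and `fdr < fdrMax`, and `not_significant`
#' otherwise. Boundaries are inclusive on the fold change and strict on the
#' FDR. Every record receives exactly one call.
#'
#' @param x a [DEGTable-class], or a numeric vector of log2 fold changes.
#' @param fdr numeric vector of FDR values (only when `x` is numeric).
#' @param lfcMin fold-change threshold on the log2 scale (default 2).
#' @param fdrMax strict FDR bound (default 0.05).
#' @return for a `DEGTable`, the same table with a `call` column; for
#'   numeric input, a character vector of calls.
#' @export
#' @examples
#' classifyDEG(c(2.5, -2.5, 1.99), fdr = c(0.01, 0.01, 0.001))
classifyDEG <- function(x, fdr = NULL, lfcMin = 2, fdrMax = 0.05) {
  stopifnot(lfcMin >= 0, fdrMax >= 0)
  if (is(x, "DEGTable")) {
    tab <- x@table
    tab$call <- classifyCalls(tab$log2fc, tab$fdr, lfcMin, fdrMax)
    return(new("DEGTable", table = tab))
  }
  if (!is.numeric(x) || is.null(fdr))
    stop("supply a DEGTable, or numeric log2fc plus fdr vectors", call. = FALSE)
  classifyCalls(x, fdr, lfcMin, fdrMax)
}

classifyCalls <- function(log2fc, fdr, lfcMin, fdrMax) {
  if (any(!is.finite(log2fc)) || any(!is.finite(fdr)))
    stop("log2fc and fdr must be finite", call. = FALSE)
  sig <- fdr < fdrMax
  ifelse(sig & log2fc >= lfcMin, "up",
         ifelse(sig & log2fc <= -lfcMin, "down", "not_significant"))
}

#' Regulated gene sets of a classified DEG table
#'
#' @param x a classified [DEGTable-class] (with a `call` column).
#' @param direction `"up"` or `"down"`.
#' @return character vector of gene ids with the requested call.
#' @export
regulatedGenes <- function(x, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is(x, "DEGTable"))
  if (!"call" %in% names(x@table))
    stop("DEGTable is unclassified; run classifyDEG() first", call. = FALSE)
  x@table$gene_id[x@table$call == direction]
}
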