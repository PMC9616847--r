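#' Gene identifiers of an object
#'
#' @param x a `DEGTable`, `PPINetwork`, `AnnotationSet` or `GeneRankTable`.
#' @return character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname geneIds
#' @export
setMethod("geneIds", "DEGTable", function(x) x@table$gene_id)

#' @rdname geneIds
#' @export
setMethod("geneIds", "PPINetwork", function(x) {
  if (igraph::vcount(x@graph) == 0L) character(0) else igraph::V(x@graph)$name
})

#' @rdname geneIds
#' @export
setMethod("geneIds", "AnnotationSet", function(x) unique(x@annotations$gene_id))

#' @rdname geneIds
#' @export
setMethod("geneIds", "GeneRankTable", function(x) x@table$gene_id)

#' Node and edge counts of a network
#'
#' @param x a `PPINetwork`.
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "PPINetwork", function(x) igraph::vcount(x@graph))

#' @rdname nNodes
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname nNodes
#' @export
setMethod("nEdges", "PPINetwork", function(x) igraph::ecount(x@graph))

#' Underlying igraph of a PPINetwork
#'
#' @param x a `PPINetwork`.
#' @return the wrapped \pkg{igraph} object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "PPINetwork", function(x) x@graph)

#' Clusters of a ClusterSet
#'
#' @param x a `ClusterSet`.
#' @return list of cluster records.
#' @export
setGeneric("clusterList", function(x) standardGeneric("clusterList"))

#' @rdname clusterList
#' @export
setMethod("clusterList", "ClusterSet", function(x) x@clusters)

#' @export
setMethod("length", "ClusterSet", function(x) length(x@clusters))

#' Coerce pipeline objects to data.frame
#'
#' @param x object to coerce.
#' @param row.names,optional ignored, present for generic compatibility.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "DEGTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

#' @rdname as.data.frame-DEGTable-method
#' @export
setMethod("as.data.frame", "AnnotationSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@annotations)

#' @rdname as.data.frame-DEGTable-method
#' @export
setMethod("as.data.frame", "GeneRankTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@table)

#' @rdname as.data.frame-DEGTable-method
#' @export
setMethod("as.data.frame", "ClusterSet",
          function(x, row.names = NULL, optional = FALSE, ...) {
    if (length(x@clusters) == 0L)
      return(data.frame(cluster = integer(0), gene_id = character(0),
                        is_seed = logical(0), is_fluffed = logical(0)))
    do.call(rbind, lapply(seq_along(x@clusters), function(i) {
      cl <- x@clusters[[i]]
      data.frame(cluster = i, gene_id = cl$members,
                 is_seed = cl$members == cl$seed,
                 is_fluffed = cl$members %in% cl$fluffed,
                 stringsAsFactors = FALSE)
    }))
})

setMethod("show", "DEGTable", function(object) {
  tab <- object@table
  cat(sprintf("DEGTable with %d genes\n", nrow(tab)))
  if ("call" %in% names(tab)) {
    counts <- table(factor(tab$call, levels = REGULATION_CALLS))
    cat(sprintf("  up: %d  down: %d  not_significant: %d\n",
                counts[["up"]], counts[["down"]], counts[["not_significant"]]))
  } else {
    cat("  (unclassified; run classifyDEG())\n")
  }
})

setMethod("show", "PPINetwork", function(object) {
  cat(sprintf("PPINetwork: %d nodes, %d edges\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
})

setMethod("show", "AnnotationSet", function(object) {
  ann <- object@annotations
  cat(sprintf("AnnotationSet: %d memberships, %d terms, %d genes\n",
              nrow(ann), length(unique(ann$term_id)),
              length(unique(ann$gene_id))))
  for (ns in intersect(GO_NAMESPACES, unique(ann$namespace)))
    cat(sprintf("  %s: %d terms\n", ns,
                length(unique(ann$term_id[ann$namespace == ns]))))
})

setMethod("show", "GeneRankTable", function(object) {
  cat(sprintf("GeneRankTable: %d genes over namespaces %s\n",
              nrow(object@table), paste(object@namespaces, collapse = "/")))
  if ("selected_round1" %in% names(object@table))
    cat(sprintf("  selected at >= %g%% average percentile: %d\n",
                object@cutoff, sum(object@table$selected_round1)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet with %d cluster(s)\n", length(object@clusters)))
  for (i in seq_along(object@clusters)) {
    cl <- object@clusters[[i]]
    cat(sprintf("  %d: n=%d e=%d density=%.3f score=%.3f seed=%s\n",
                i, cl$n, cl$e, cl$density, cl$score, cl$seed))
  }
})

setMethod("show", "MCODEParams", function(object) {
  cat(sprintf(
    "MCODEParams: nodeScoreCutoff=%g kCore=%d haircut=%s fluff=%s (density %g)\n",
    object@nodeScoreCutoff, object@kCore, object@haircut, object@fluff,
    object@fluffDensity))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d genes (%.0f%% up, %.0f%% down), %d module(s), pOut=%g, seed=%d\n",
    object@nGenes, 100 * object@fracUp, 100 * object@fracDown,
    length(object@modules), object@pOut, object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d up, %d down, %d planted module(s), %d planted term(s)\n",
    length(object@upGenes), length(object@downGenes),
    length(object@modules), length(object@plantedTermIds)))
})
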