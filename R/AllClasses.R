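#' @import methods
#' @importFrom stats phyper p.adjust rnorm runif sd setNames
#' @importFrom utils read.delim write.table
NULL

setOldClass("igraph")

REGULATION_CALLS <- c("up", "down", "not_significant")
GO_NAMESPACES <- c("BP", "CC", "MF")

#' DEGTable: a table of differential-expression evidence
#'
#' One row per gene, holding the log2 fold-change and FDR from an upstream
#' differential-expression analysis, plus (once classified) the regulation
#' call. Gene identifiers are opaque, case-sensitive strings and must be
#' unique.
#'
#' @slot table a `data.frame` with columns `gene_id` (character),
#'   `log2fc` (numeric), `fdr` (numeric in \[0, 1\]) and optionally
#'   `call` (one of `"up"`, `"down"`, `"not_significant"`).
#' @export
setClass("DEGTable", representation(table = "data.frame"))

setValidity("DEGTable", function(object) {
  tab <- object@table
  needed <- c("gene_id", "log2fc", "fdr")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L)
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (!is.character(tab$gene_id)) return("gene_id must be character")
  if (anyDuplicated(tab$gene_id))
    return(sprintf("duplicate gene_id: %s",
                   paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", ")))
  if (!is.numeric(tab$log2fc) || !is.numeric(tab$fdr))
    return("log2fc and fdr must be numeric")
  if (any(!is.finite(tab$fdr)) || any(tab$fdr < 0 | tab$fdr > 1))
    return("fdr values must be finite and in [0, 1]")
  if ("call" %in% names(tab) && !all(tab$call %in% REGULATION_CALLS))
    return("call values must be one of up/down/not_significant")
  TRUE
})

#' PPINetwork: an undirected, evidence-scored interaction network
#'
#' Wraps a simple undirected \pkg{igraph} graph whose vertices are gene ids
#' and whose edges carry a STRING-style `combined_score`. Self-loops and
#' multi-edges are disallowed; readers collapse duplicate unordered pairs
#' keeping the maximum score.
#'
#' @slot graph an \pkg{igraph} object (undirected, simple, named vertices,
#'   numeric `combined_score` edge attribute).
#' @export
setClass("PPINetwork", representation(graph = "igraph"))

setValidity("PPINetwork", function(object) {
  g <- object@graph
  if (igraph::is_directed(g)) return("graph must be undirected")
  if (!igraph::is_simple(g)) return("graph must be simple (no loops/multi-edges)")
  if (igraph::vcount(g) > 0L && is.null(igraph::V(g)$name))
    return("vertices must be named")
  if (igraph::ecount(g) > 0L) {
    cs <- igraph::E(g)$combined_score
    if (is.null(cs)) return("edges must carry a combined_score attribute")
    if (any(!is.finite(cs)) || any(cs < 0))
      return("combined_score must be finite and >= 0")
  }
  TRUE
})

#' AnnotationSet: flat gene-to-GO-term memberships with background counts
#'
#' One row per (term, gene) membership, within one of the three Gene Ontology
#' namespaces (BP, CC, MF). Each row also carries the term's background count
#' (annotated genes in the reference population) and the population background
#' count, which together define the hypergeometric reference for enrichment.
#' No DAG structure is represented: term-gene tables are treated as flat.
#'
#' @slot annotations a `data.frame` with columns `term_id`, `namespace`
#'   (BP/CC/MF), `gene_id`, `term_background_count`,
#'   `population_background_count`.
#' @export
setClass("AnnotationSet", representation(annotations = "data.frame"))

setValidity("AnnotationSet", function(object) {
  ann <- object@annotations
  needed <- c("term_id", "namespace", "gene_id",
              "term_background_count", "population_background_count")
  missing <- setdiff(needed, names(ann))
  if (length(missing) > 0L)
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (!all(ann$namespace %in% GO_NAMESPACES))
    return("namespace must be one of BP, CC, MF")
  tb <- ann$term_background_count
  pb <- ann$population_background_count
  if (any(tb < 1L) || any(pb < 1L))
    return("background counts must be >= 1")
  if (any(tb > pb))
    return("term_background_count must not exceed population_background_count")
  if (anyDuplicated(ann[c("term_id", "namespace", "gene_id")]))
    return("duplicate (term_id, namespace, gene_id) rows")
  TRUE
})

#' GeneRankTable: round-1 GO percentile ranking of regulated genes
#'
#' Per-gene summed GO scores and percentile ranks per namespace, the average
#' percentile across the namespaces the gene occupies, and the round-1
#' selection flag.
#'
#' @slot table a `data.frame` with `gene_id`, `score_<ns>` and
#'   `percentile_<ns>` per namespace, `average_percentile`,
#'   `selected_round1`.
#' @slot namespaces character, the namespaces that contributed.
#' @slot cutoff numeric, the percentile cutoff used for the round-1 screen.
#' @export
setClass("GeneRankTable",
         representation(table = "data.frame", namespaces = "character",
                        cutoff = "numeric"))

setValidity("GeneRankTable", function(object) {
  tab <- object@table
  if (!"gene_id" %in% names(tab)) return("missing gene_id column")
  if (!"average_percentile" %in% names(tab)) return("missing average_percentile")
  ap <- tab$average_percentile
  if (length(ap) > 0L && (any(ap < 0 | ap > 100, na.rm = TRUE)))
    return("average_percentile must lie in [0, 100]")
  TRUE
})

#' MCODEParams: parameters of the molecular-complex detection step
#'
#' Defaults follow the settings used throughout this pipeline: node score
#' cutoff 0.2 and kappa-core 2, with the density cutoff kept at 0.1 for the
#' optional fluff post-processing step (off by default, the detector's
#' factory default; the reported clusters are then pairwise node-disjoint).
#'
#' @slot nodeScoreCutoff numeric in \[0, 1\]; a neighbour joins a growing
#'   complex if its weight exceeds `seedWeight * (1 - nodeScoreCutoff)`.
#' @slot kCore integer >= 2; complexes lacking a k-core of this order are
#'   discarded.
#' @slot fluff logical; add boundary neighbours whose closed-neighbourhood
#'   density exceeds `fluffDensity` (such nodes may belong to several
#'   clusters and are flagged).
#' @slot fluffDensity numeric in \[0, 1\].
#' @slot haircut logical; iteratively remove degree-1 members.
#' @slot maxDepth integer >= 1; how many hops from the seed the expansion
#'   explores (default 1: a complex grows within the seed's neighbourhood).
#' @export
setClass("MCODEParams",
         representation(nodeScoreCutoff = "numeric", kCore = "integer",
                        fluff = "logical", fluffDensity = "numeric",
                        haircut = "logical", maxDepth = "integer"),
         prototype(nodeScoreCutoff = 0.2, kCore = 2L, fluff = FALSE,
                   fluffDensity = 0.1, haircut = FALSE, maxDepth = 1L))

setValidity("MCODEParams", function(object) {
  if (object@nodeScoreCutoff < 0 || object@nodeScoreCutoff > 1)
    return("nodeScoreCutoff must lie in [0, 1]")
  if (object@kCore < 2L) return("kCore must be >= 2")
  if (object@fluffDensity < 0 || object@fluffDensity > 1)
    return("fluffDensity must lie in [0, 1]")
  if (object@maxDepth < 1L) return("maxDepth must be >= 1")
  TRUE
})

#' ClusterSet: detected molecular complexes
#'
#' An ordered list of clusters (decreasing score). Each cluster records its
#' member genes, node and internal-edge counts, density `2e / (n (n - 1))`,
#' score `density * n`, the seed gene, and which members were added by the
#' fluff step.
#'
#' @slot clusters a list; each element is a list with fields `members`,
#'   `n`, `e`, `density`, `score`, `seed`, `fluffed`.
#' @export
setClass("ClusterSet", representation(clusters = "list"))

setValidity("ClusterSet", function(object) {
  for (cl in object@clusters) {
    needed <- c("members", "n", "e", "density", "score", "seed", "fluffed")
    if (!all(needed %in% names(cl))) return("cluster missing fields")
    if (cl$n != length(cl$members)) return("cluster n inconsistent with members")
    if (cl$density < 0 || cl$density > 1) return("density must lie in [0, 1]")
  }
  TRUE
})

#' SyntheticSpec: parameters of the synthetic study generator
#'
#' Describes a synthetic study: a DEG universe with stated up/down fractions,
#' an interaction network with dense planted modules over a sparse
#' Erdos-Renyi background, and flat GO annotations with terms deliberately
#' over-represented in the up-regulated set. All randomness flows from
#' `seed`.
#'
#' @slot nGenes integer, size of the gene universe.
#' @slot fracUp,fracDown fractions of up-/down-regulated genes (sum <= 1).
#' @slot lfcLocation,lfcScale location/scale of the half-normal shift added
#'   to the fold-change floor of 2, so regulated genes satisfy
#'   `|log2fc| >= 2` by construction.
#' @slot fdrSigMax regulated genes draw FDR uniformly on (0, fdrSigMax).
#' @slot modules list of `list(size =, pIn =)` planted dense modules
#'   (disjoint, placed on up-regulated genes when possible).
#' @slot pOut background edge probability (must be < every module pIn).
#' @slot nTerms integer, background GO terms per namespace.
#' @slot plantedTerms list of `list(namespace =, size =, fracUp =)` terms
#'   enriched in the up-regulated set by construction.
#' @slot seed integer RNG seed.
#' @export
setClass("SyntheticSpec",
         representation(nGenes = "integer", fracUp = "numeric",
                        fracDown = "numeric", lfcLocation = "numeric",
                        lfcScale = "numeric", fdrSigMax = "numeric",
                        modules = "list", pOut = "numeric",
                        nTerms = "integer", plantedTerms = "list",
                        seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  if (object@nGenes < 1L) return("nGenes must be >= 1")
  probs <- c(object@fracUp, object@fracDown, object@pOut, object@fdrSigMax)
  if (any(probs < 0) || any(probs > 1)) return("probabilities must lie in [0, 1]")
  if (object@fracUp + object@fracDown > 1)
    return("fracUp + fracDown must not exceed 1")
  for (m in object@modules) {
    if (m$size < 3L) return("module sizes must be >= 3")
    if (m$pIn <= object@pOut) return("module pIn must exceed pOut")
    if (m$pIn > 1) return("module pIn must lie in [0, 1]")
  }
  if (sum(vapply(object@modules, function(m) m$size, numeric(1))) > object@nGenes)
    return("planted module sizes exceed nGenes")
  for (t in object@plantedTerms) {
    if (!t$namespace %in% GO_NAMESPACES) return("planted term namespace invalid")
    if (t$size > object@nGenes) return("planted term larger than gene universe")
    if (t$fracUp < 0 || t$fracUp > 1) return("planted fracUp must lie in [0, 1]")
  }
  TRUE
})

#' GroundTruth: what the synthetic generator planted
#'
#' @slot upGenes,downGenes character vectors of regulated gene ids.
#' @slot modules list of character vectors, the planted module node sets.
#' @slot plantedTermIds character, ids of the deliberately enriched terms.
#' @export
setClass("GroundTruth",
         representation(upGenes = "character", downGenes = "character",
                        modules = "list", plantedTermIds = "character"))

setValidity("GroundTruth", function(object) {
  if (length(intersect(object@upGenes, object@downGenes)) > 0L)
    return("a gene cannot be both up- and down-regulated")
  TRUE
})
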