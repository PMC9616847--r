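## Molecular-complex detection: local-core vertex weighting, greedy seeded
## expansion, k-core filtering, optional fluff/haircut post-processing, and
## density-times-size cluster scoring.

#' MCODE parameter object
#'
#' @param nodeScoreCutoff neighbour-admission cutoff (default 0.2): a
#'   neighbour joins when its weight exceeds `seedWeight * (1 - cutoff)`.
#' @param kCore minimum core order a complex must contain (default 2).
#' @param fluff add boundary neighbours whose closed-neighbourhood density
#'   exceeds `fluffDensity` (default `FALSE`; fluffed nodes may belong to
#'   several clusters).
#' @param fluffDensity density threshold for fluff (default 0.1).
#' @param haircut iteratively remove degree-1 members (default `FALSE`).
#' @param maxDepth expansion radius in hops from the seed (default 1).
#' @return an [MCODEParams-class].
#' @export
mcodeParams <- function(nodeScoreCutoff = 0.2, kCore = 2L, fluff = FALSE,
                        fluffDensity = 0.1, haircut = FALSE, maxDepth = 1L) {
  new("MCODEParams", nodeScoreCutoff = nodeScoreCutoff,
      kCore = as.integer(kCore), fluff = fluff,
      fluffDensity = fluffDensity, haircut = haircut,
      maxDepth = as.integer(maxDepth))
}

#' Core numbers of a network
#'
#' The core number of a node is the largest k such that the node belongs to
#' the k-core (the maximal subgraph with minimum degree k).
#'
#' @param network a [PPINetwork-class] or an \pkg{igraph} graph.
#' @return named integer vector of core numbers.
#' @export
coreNumber <- function(network) {
  g <- if (is(network, "PPINetwork")) network@graph else network
  if (igraph::vcount(g) == 0L) return(setNames(integer(0), character(0)))
  k <- igraph::coreness(g)
  setNames(as.integer(k), igraph::V(g)$name)
}

## density of a simple undirected graph: 2e / (n (n - 1)); n < 2 -> 0
graphDensity <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' The weight of a node is `k * density(C)` where, within the subgraph
#' induced by the node's closed neighbourhood, `k` is the highest core order
#' present and `C` is that highest k-core. Isolated nodes weigh 0.
#'
#' @param network a [PPINetwork-class] or an \pkg{igraph} graph.
#' @param nodes optional subset of node names (default: all).
#' @return named numeric vector of weights.
#' @export
vertexWeight <- function(network, nodes = NULL) {
  g <- if (is(network, "PPINetwork")) network@graph else network
  allNames <- if (igraph::vcount(g) > 0L) igraph::V(g)$name else character(0)
  if (is.null(nodes)) nodes <- allNames
  adj <- igraph::as_adj_list(g)
  names(adj) <- allNames
  w <- setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    nbrs <- allNames[as.integer(adj[[v]])]
    if (length(nbrs) == 0L) next
    H <- igraph::induced_subgraph(g, c(v, nbrs))
    core <- igraph::coreness(H)
    k <- max(core)
    C <- igraph::induced_subgraph(H, which(core == k))
    w[v] <- k * graphDensity(C)
  }
  w
}

#' Density and score of a cluster from node and edge counts
#'
#' `density = 2e / (n (n - 1))` and `score = density * n`, the cluster
#' score reported by molecular-complex detection (a 16-node cluster with 66
#' internal edges scores 8.8).
#'
#' @param n node count (>= 2).
#' @param e internal edge count, at most `n (n - 1) / 2`.
#' @return a list with `density` and `score`.
#' @export
#' @examples
#' clusterScore(16, 66)  # density 0.55, score 8.8
clusterScore <- function(n, e) {
  if (n < 2L) stop("a scored cluster needs at least 2 nodes", call. = FALSE)
  if (e < 0 || e > n * (n - 1) / 2)
    stop("edge count exceeds the simple-graph maximum", call. = FALSE)
  density <- 2 * e / (n * (n - 1))
  list(density = density, score = density * n)
}

#' Detect dense complexes (MCODE-style)
#'
#' Greedy seeded expansion over MCODE vertex weights: seeds are taken in
#' decreasing weight (ties broken by lexicographic node id); a neighbour of
#' the growing complex joins if it is unassigned, lies within `maxDepth`
#' hops of the seed, and its weight exceeds
#' `seedWeight * (1 - nodeScoreCutoff)`. Complexes lacking a k-core of
#' order `kCore` are discarded. Optional post-processing: haircut
#' iteratively removes degree-1 members, then fluff adds boundary
#' neighbours whose closed-neighbourhood density exceeds `fluffDensity`
#' (fluffed nodes are flagged, stay eligible for later clusters, and may
#' appear in several). Clusters are reported in decreasing score order
#' (`score = density * n`).
#'
#' @param network a [PPINetwork-class] or an \pkg{igraph} graph.
#' @param params an [MCODEParams-class] (defaults: node score cutoff 0.2,
#'   k-core 2, no fluff, no haircut).
#' @return a [ClusterSet-class] (empty for an empty graph).
#' @export
findComplexes <- function(network, params = mcodeParams()) {
  g <- if (is(network, "PPINetwork")) network@graph else network
  stopifnot(is(params, "MCODEParams"))
  n <- igraph::vcount(g)
  if (n == 0L) return(new("ClusterSet", clusters = list()))
  ids <- igraph::V(g)$name
  if (is.null(ids)) {
    ids <- as.character(seq_len(n))
    igraph::V(g)$name <- ids
  }
  w <- vertexWeight(g)
  adj <- igraph::as_adj_list(g)
  names(adj) <- ids
  neighbourNames <- lapply(adj, function(x) ids[as.integer(x)])
  ## seed order: decreasing weight, lexicographic id on ties
  seedOrder <- ids[order(-w[ids], ids)]
  assigned <- setNames(logical(n), ids)
  clusters <- list()
  for (seed in seedOrder) {
    if (assigned[seed]) next
    threshold <- w[seed] * (1 - params@nodeScoreCutoff)
    members <- character(0)
    queue <- seed
    depth <- setNames(0L, seed)
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (assigned[v] || v %in% members) next
      if (v != seed && w[v] <= threshold) next
      members <- c(members, v)
      if (depth[v] < params@maxDepth) {
        fresh <- setdiff(neighbourNames[[v]], c(members, names(depth)))
        if (length(fresh) > 0L) {
          depth[fresh] <- depth[v] + 1L
          queue <- c(queue, fresh)
        }
      }
    }
    assigned[members] <- TRUE
    core <- igraph::coreness(igraph::induced_subgraph(g, members))
    if (max(core) < params@kCore) next
    if (params@haircut) {
      repeat {
        sub <- igraph::induced_subgraph(g, members)
        degs <- igraph::degree(sub)
        drop <- igraph::V(sub)$name[degs < 2]
        if (length(drop) == 0L) break
        members <- setdiff(members, drop)
      }
      if (length(members) < 2L) next
    }
    fluffed <- character(0)
    if (params@fluff) {
      boundary <- setdiff(unique(unlist(neighbourNames[members])), members)
      for (u in boundary) {
        H <- igraph::induced_subgraph(g, c(u, neighbourNames[[u]]))
        if (graphDensity(H) > params@fluffDensity) fluffed <- c(fluffed, u)
      }
      members <- c(members, sort(fluffed))
    }
    sub <- igraph::induced_subgraph(g, members)
    nM <- igraph::vcount(sub); eM <- igraph::ecount(sub)
    cs <- if (nM >= 2L) clusterScore(nM, eM) else list(density = 0, score = 0)
    clusters[[length(clusters) + 1L]] <- list(
      members = sort(members), n = nM, e = eM, density = cs$density,
      score = cs$score, seed = seed, fluffed = sort(fluffed))
  }
  if (length(clusters) > 1L) {
    ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
                 vapply(clusters, `[[`, character(1), "seed"))
    clusters <- clusters[ord]
  }
  new("ClusterSet", clusters = clusters)
}
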