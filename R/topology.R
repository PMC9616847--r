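## Round-2 screening: induced subnetwork of round-1 survivors, six node
## centralities on unweighted shortest paths, percentile-normalized
## composite, selection at the average-percentile mark.

#' Induced subnetwork on a gene set
#'
#' Node set is the intersection of `genes` with the network's nodes; edges
#' are all network edges with both endpoints in that set.
#'
#' @param network a [PPINetwork-class].
#' @param genes character vector of gene ids.
#' @return a [PPINetwork-class]; an empty intersection gives an empty graph
#'   with a warning.
#' @export
inducedSubnetwork <- function(network, genes) {
  stopifnot(is(network, "PPINetwork"))
  keep <- intersect(unique(genes), geneIds(network))
  if (length(keep) == 0L) {
    warning("no requested genes are present in the network")
    return(new("PPINetwork",
               graph = igraph::make_empty_graph(0, directed = FALSE)))
  }
  new("PPINetwork", graph = igraph::induced_subgraph(network@graph, keep))
}

#' Six node centralities on unweighted shortest paths
#'
#' Computes, per node: degree; betweenness (unnormalized, summed over
#' unordered pairs `s < t`, fractional over shortest-path multiplicity);
#' stress (the count of shortest paths passing through the node); closeness
#' `(n_c - 1) / sum d(v, u)` within the node's component of size `n_c`;
#' radiality `sum_u (diam_c + 1 - d(v, u)) / (n_c - 1)` with the component
#' diameter; and eigenvector centrality, the principal adjacency eigenvector
#' of each component scaled to unit Euclidean norm. Components are handled
#' independently; edge scores are ignored (unweighted paths); nodes in
#' singleton components score 0 on every metric by convention.
#'
#' @param network a [PPINetwork-class] or an \pkg{igraph} graph.
#' @return a `data.frame` with columns `gene_id`, `degree`, `betweenness`,
#'   `closeness`, `radiality`, `stress`, `eigenvector`.
#' @export
computeCentralities <- function(network) {
  g <- if (is(network, "PPINetwork")) network@graph else network
  n <- igraph::vcount(g)
  ids <- if (n > 0L) igraph::V(g)$name else character(0)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 0L) {
    return(data.frame(gene_id = character(0), degree = integer(0),
                      betweenness = numeric(0), closeness = numeric(0),
                      radiality = numeric(0), stress = numeric(0),
                      eigenvector = numeric(0)))
  }
  deg <- as.integer(igraph::degree(g))
  btw <- igraph::betweenness(g, weights = NA, normalized = FALSE)
  D <- igraph::distances(g, weights = NA)
  comp <- igraph::components(g)
  closeness <- radiality <- eigenvec <- numeric(n)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    nc <- length(members)
    if (nc == 1L) next  # singleton: all metrics 0 by convention
    Dc <- D[members, members, drop = FALSE]
    diam <- max(Dc)
    closeness[members] <- (nc - 1) / rowSums(Dc)
    radiality[members] <- (rowSums(diam + 1 - Dc) - (diam + 1)) / (nc - 1)
    A <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, members), sparse = FALSE)
    ev <- eigen(A, symmetric = TRUE)
    v1 <- abs(ev$vectors[, 1])        # Perron vector, unit Euclidean norm
    eigenvec[members] <- v1
  }
  stress <- stressCentrality(g, D)
  data.frame(gene_id = ids, degree = deg, betweenness = as.numeric(btw),
             closeness = closeness, radiality = radiality, stress = stress,
             eigenvector = eigenvec, stringsAsFactors = FALSE)
}

## Stress centrality: number of shortest paths through each node, summed
## over unordered source-target pairs. sigma[s, v] (shortest-path counts) is
## accumulated per source in breadth-first distance order; a path s..t runs
## through v iff d(s,v) + d(v,t) = d(s,t), contributing sigma[s,v]*sigma[v,t].
stressCentrality <- function(g, D = NULL) {
  n <- igraph::vcount(g)
  if (n == 0L) return(numeric(0))
  if (is.null(D)) D <- igraph::distances(g, weights = NA)
  adj <- igraph::as_adj_list(g)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- D[s, ]
    sigma[s, s] <- 1
    reach <- which(is.finite(d) & d > 0)
    for (v in reach[order(d[reach])]) {
      pred <- as.integer(adj[[v]])
      pred <- pred[d[pred] == d[v] - 1]
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  stress <- numeric(n)
  for (v in seq_len(n)) {
    dsv <- D[, v]
    for (s in seq_len(n - 1L)) {
      if (s == v || !is.finite(dsv[s])) next
      t <- seq.int(s + 1L, n)
      t <- t[t != v & is.finite(D[s, t]) & dsv[s] + dsv[t] == D[s, t]]
      if (length(t) > 0L)
        stress[v] <- stress[v] + sum(sigma[s, v] * sigma[v, t])
    }
  }
  stress
}

#' Composite topological score
#'
#' Each of the six centralities is converted to a percentile rank across all
#' nodes (the same inclusive empirical-CDF definition as the round-1 GO
#' ranking) and the composite is their mean, so integer-valued metrics such
#' as stress cannot dominate real-valued ones through scale alone.
#'
#' @param centralities output of [computeCentralities()].
#' @return the input `data.frame` with added `percentile_<metric>` columns
#'   and a `composite_score` column in \[0, 100\].
#' @export
compositeTopologyScore <- function(centralities) {
  metrics <- c("degree", "betweenness", "closeness", "radiality",
               "stress", "eigenvector")
  stopifnot(all(c("gene_id", metrics) %in% names(centralities)))
  out <- centralities
  if (nrow(out) == 0L) {
    out$composite_score <- numeric(0)
    return(out)
  }
  pct <- vapply(metrics,
                function(m) percentileRank(out[[m]]),
                numeric(nrow(out)))
  pct <- matrix(pct, nrow = nrow(out),
                dimnames = list(NULL, paste0("percentile_", metrics)))
  out <- cbind(out, pct)
  out$composite_score <- rowMeans(pct)
  out
}

#' Round-2 selection at the average-percentile mark
#'
#' Defaults to retaining genes whose composite score is at or above the
#' mark (`rule = "ge"`, the top of the ranking); `rule = "le"` selects the
#' complementary bottom band instead.
#'
#' @param scores output of [compositeTopologyScore()].
#' @param mark percentile mark (default 50).
#' @param rule `"ge"` (composite >= mark, default) or `"le"`.
#' @return character vector of selected gene ids (sorted).
#' @export
selectRound2 <- function(scores, mark = 50, rule = c("ge", "le")) {
  rule <- match.arg(rule)
  stopifnot(all(c("gene_id", "composite_score") %in% names(scores)))
  keep <- if (rule == "ge") scores$composite_score >= mark
          else scores$composite_score <= mark
  sort(scores$gene_id[keep])
}
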