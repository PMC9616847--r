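# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: shortest paths are found by enumerating all
# simple paths, hypergeometric tails by enumerating draw subsets, and the
# principal eigenvector by shifted power iteration.

makeNetwork <- function(a, b, score = 1) {
  ppiNetwork(data.frame(node_a = a, node_b = b, combined_score = score,
                        stringsAsFactors = FALSE))
}

completeGraphNetwork <- function(ids) {
  pr <- t(combn(ids, 2))
  makeNetwork(pr[, 1], pr[, 2])
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# all simple paths s -> t in an adjacency matrix (small n only)
allSimplePaths <- function(adj, s, t) {
  paths <- list()
  walk <- function(v, visited) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible())
    }
    for (u in which(adj[v, ] == 1)) {
      if (!(u %in% visited)) walk(u, c(visited, u))
    }
  }
  walk(s, s)
  paths
}

# brute-force reference for all six centralities (exhaustive path count)
bruteCentralities <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  btw <- stress <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      ps <- allSimplePaths(adj, s, t)
      if (length(ps) == 0L) next
      lens <- vapply(ps, length, integer(1))
      d <- min(lens) - 1L
      D[s, t] <- D[t, s] <- d
      sp <- ps[lens == d + 1L]
      for (v in setdiff(seq_len(n), c(s, t))) {
        cnt <- sum(vapply(sp, function(p) v %in% p, logical(1)))
        stress[v] <- stress[v] + cnt
        btw[v] <- btw[v] + cnt / length(sp)
      }
    }
  }
  closeness <- radiality <- eig <- numeric(n)
  seen <- rep(FALSE, n)
  for (v in seq_len(n)) {
    if (seen[v]) next
    members <- which(is.finite(D[v, ]))
    seen[members] <- TRUE
    nc <- length(members)
    if (nc == 1L) next
    Dc <- D[members, members, drop = FALSE]
    diam <- max(Dc)
    for (m in seq_along(members)) {
      i <- members[m]
      closeness[i] <- (nc - 1) / sum(Dc[m, ])
      radiality[i] <- (sum(diam + 1 - Dc[m, ]) - (diam + 1)) / (nc - 1)
    }
    A <- adj[members, members, drop = FALSE] + diag(nc)  # shift: bipartite-safe
    x <- rep(1, nc)
    for (it in 1:100000) {
      x2 <- as.numeric(A %*% x)
      x2 <- x2 / sqrt(sum(x2^2))
      if (max(abs(x2 - x)) < 1e-14) { x <- x2; break }
      x <- x2
    }
    eig[members] <- abs(x)
  }
  data.frame(degree = rowSums(adj), betweenness = btw,
             closeness = closeness, radiality = radiality,
             stress = stress, eigenvector = eig)
}

# random connected graph on n nodes as an adjacency matrix
randomConnectedAdj <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    for (s in seq_len(n - 1L)) {
      for (t in seq.int(s + 1L, n)) {
        if (runif(1) < p) adj[s, t] <- adj[t, s] <- 1L
      }
    }
    D <- adj
    reach <- diag(n) + adj
    for (k in seq_len(n)) reach <- reach %*% (diag(n) + adj)
    if (all(reach[1, ] > 0)) return(adj)
  }
}

adjToNetwork <- function(adj, ids = sprintf("n%02d", seq_len(nrow(adj)))) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  makeNetwork(ids[idx[, 1]], ids[idx[, 2]])
}

# exhaustive hypergeometric upper tail: enumerate every draw subset
bruteHypergeomUpper <- function(obs, draws, K, N) {
  pop <- c(rep(1L, K), rep(0L, N - K))
  subsets <- combn(N, draws)
  hits <- apply(subsets, 2, function(ix) sum(pop[ix]) >= obs)
  mean(hits)
}

# small annotation fixture builder
annotationSetFromList <- function(termGenes, namespace, termBg = NULL,
                                  popBg = 1000L) {
  rows <- do.call(rbind, lapply(names(termGenes), function(tid) {
    data.frame(term_id = tid, namespace = namespace,
               gene_id = termGenes[[tid]], stringsAsFactors = FALSE)
  }))
  if (is.null(termBg))
    termBg <- vapply(termGenes, length, integer(1))
  rows$term_background_count <- as.integer(termBg[rows$term_id])
  rows$population_background_count <- as.integer(popBg)
  new("AnnotationSet", annotations = rows)
}
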