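test_that("core numbers match peel-by-degree expectations", {
  k4 <- completeGraphNetwork(paste0("k", 1:4))
  expect_equal(unname(coreNumber(k4)), rep(3L, 4))
  path <- makeNetwork(paste0("p", 1:4), paste0("p", 2:5))
  expect_equal(unname(coreNumber(path)), rep(1L, 5))
  # peel oracle on a random graph: repeatedly remove min-degree vertices
  set.seed(97)
  adj <- randomConnectedAdj(9, 0.4)
  ids <- sprintf("n%02d", 1:9)
  got <- coreNumber(adjToNetwork(adj, ids))[ids]
  peel <- function(adj) {
    n <- nrow(adj)
    core <- integer(n)
    alive <- rep(TRUE, n)
    k <- 0L
    while (any(alive)) {
      repeat {
        deg <- rowSums(adj[, alive, drop = FALSE])[alive]
        low <- which(alive)[deg <= k]
        if (length(low) == 0L) break
        core[low] <- k
        alive[low] <- FALSE
        if (!any(alive)) break
      }
      k <- k + 1L
    }
    core
  }
  expect_equal(unname(got), peel(adj))
})

test_that("vertex weights are core order times core density", {
  k4 <- completeGraphNetwork(paste0("k", 1:4))
  expect_equal(unname(vertexWeight(k4)), rep(3, 4))
  # star S5: closed neighborhood of the hub is the whole star, highest core
  # is the 1-core (the star itself), density 2*5/(6*5)
  star <- makeNetwork(rep("H", 5), paste0("L", 1:5))
  w <- vertexWeight(star)
  expect_equal(unname(w["H"]), 1 * (2 * 5) / (6 * 5))
  # leaves: closed neighborhood H-L edge only, density 1
  expect_equal(unname(w["L1"]), 1)
  # isolated node weighs zero
  iso <- new("PPINetwork",
             graph = igraph::make_empty_graph(0, directed = FALSE) +
               igraph::vertices("solo"))
  expect_equal(unname(vertexWeight(iso)), 0)
})

test_that("cluster scoring is density times size with domain checks", {
  expect_equal(clusterScore(2, 1), list(density = 1, score = 2))
  expect_equal(clusterScore(6, 14)$score, 2 * 14 / (6 * 5) * 6)
  expect_error(clusterScore(4, 7), "exceed")
  expect_error(clusterScore(1, 0), "at least 2")
})

test_that("two bridged K4s yield two separate complexes at defaults", {
  a <- t(combn(paste0("A", 1:4), 2))
  b <- t(combn(paste0("B", 1:4), 2))
  net <- makeNetwork(c(a[, 1], b[, 1], "A4"), c(a[, 2], b[, 2], "B1"))
  cs <- clusterList(findComplexes(net))
  expect_length(cs, 2L)
  expect_setequal(cs[[1]]$members, paste0("A", 1:4))
  expect_setequal(cs[[2]]$members, paste0("B", 1:4))
  expect_equal(cs[[1]]$score, 4)
  # a lone triangle is its own 2-core
  tri <- completeGraphNetwork(c("x", "y", "z"))
  cs <- clusterList(findComplexes(tri))
  expect_length(cs, 1L)
  expect_equal(cs[[1]]$n, 3L)
  expect_equal(cs[[1]]$e, 3L)
  expect_equal(cs[[1]]$score, 3)
  # empty graph: no clusters
  expect_length(findComplexes(new("PPINetwork",
    graph = igraph::make_empty_graph(0, directed = FALSE))), 0L)
})

test_that("reported clusters are connected, disjoint and deterministically ordered", {
  set.seed(101)
  syn <- generateSynthetic(syntheticSpec(
    nGenes = 150L, modules = list(list(size = 8L, pIn = 0.9),
                                  list(size = 6L, pIn = 0.9)),
    pOut = 0.03, seed = 55L))
  cs <- clusterList(findComplexes(syn$network))
  expect_gt(length(cs), 0L)
  seen <- character(0)
  scores <- vapply(cs, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 0))  # decreasing score order
  for (cl in cs) {
    sub <- asIgraph(suppressWarnings(
      inducedSubnetwork(syn$network, cl$members)))
    expect_true(igraph::is_connected(sub))
    expect_length(intersect(cl$members, seen), 0L)  # no fluff: disjoint
    seen <- c(seen, cl$members)
    # at least a 2-core present
    expect_gte(max(igraph::coreness(sub)), 2L)
  }
  # determinism: identical call, identical result
  expect_identical(clusterList(findComplexes(syn$network)), cs)
})

test_that("haircut trims pendants and fluff annotates shared boundary nodes", {
  # triangle with a pendant: low-weight pendant stays out at defaults
  net <- makeNetwork(c("a", "b", "c", "c"), c("b", "c", "a", "tail"))
  noCut <- clusterList(findComplexes(net))[[1]]
  expect_setequal(noCut$members, c("a", "b", "c"))
  # fluff: boundary node with a dense closed neighborhood joins, flagged
  fl <- clusterList(findComplexes(net, mcodeParams(fluff = TRUE,
                                                   fluffDensity = 0.1)))[[1]]
  expect_true("tail" %in% fl$members)
  expect_true("tail" %in% fl$fluffed)

  # permissive score cutoff admits a pendant into a K4 complex;
  # haircut removes it again
  k4 <- t(combn(paste0("k", 1:4), 2))
  net2 <- makeNetwork(c(k4[, 1], "k1"), c(k4[, 2], "tail"))
  loose <- clusterList(findComplexes(net2,
                                     mcodeParams(nodeScoreCutoff = 0.8)))[[1]]
  expect_true("tail" %in% loose$members)
  trimmed <- clusterList(findComplexes(net2,
    mcodeParams(nodeScoreCutoff = 0.8, haircut = TRUE)))[[1]]
  expect_setequal(trimmed$members, paste0("k", 1:4))
})

test_that("a planted dense module is recovered as the top cluster", {
  syn <- generateSynthetic(syntheticSpec(
    nGenes = 200L, modules = list(list(size = 10L, pIn = 0.95)),
    pOut = 0.02, seed = 13L))
  cs <- clusterList(findComplexes(syn$network))
  expect_gte(jaccard(cs[[1]]$members, syn$truth@modules[[1]]), 0.8)
})
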