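test_that("induced subnetworks keep exactly the internal edges", {
  tri <- makeNetwork(c("A", "B", "C"), c("B", "C", "A"))
  sub <- inducedSubnetwork(tri, c("A", "B"))
  expect_equal(nNodes(sub), 2L)
  expect_equal(nEdges(sub), 1L)
  expect_warning(empty <- inducedSubnetwork(tri, c("X", "Y")), "no requested")
  expect_equal(nNodes(empty), 0L)

  # brute double-loop edge count on a random fixture
  set.seed(41)
  adj <- randomConnectedAdj(10, 0.35)
  ids <- sprintf("n%02d", 1:10)
  net <- adjToNetwork(adj, ids)
  pick <- sample(ids, 6)
  sub <- inducedSubnetwork(net, pick)
  cnt <- 0L
  for (i in 1:9) for (j in (i + 1):10) {
    if (adj[i, j] == 1 && ids[i] %in% pick && ids[j] %in% pick)
      cnt <- cnt + 1L
  }
  expect_equal(nEdges(sub), cnt)
})

test_that("hand-enumerated centralities on path, triangle and star hold", {
  path <- makeNetwork(c("A", "B"), c("B", "C"))
  ct <- computeCentralities(path)
  b <- ct[ct$gene_id == "B", ]
  expect_equal(b$degree, 2L)
  expect_equal(b$betweenness, 1)
  expect_equal(b$stress, 1)
  expect_equal(b$closeness, 1)
  expect_equal(b$radiality, 2)

  tri <- completeGraphNetwork(c("A", "B", "C"))
  ct <- computeCentralities(tri)
  for (m in c("degree", "betweenness", "closeness", "radiality",
              "stress", "eigenvector"))
    expect_equal(ct[[m]], rep(ct[[m]][1], 3))
  expect_equal(ct$eigenvector, rep(1 / sqrt(3), 3))

  # star: every metric is maximal at the hub
  star <- makeNetwork(rep("H", 4), paste0("L", 1:4))
  ct <- computeCentralities(star)
  hub <- ct$gene_id == "H"
  for (m in c("degree", "betweenness", "closeness", "radiality",
              "stress", "eigenvector"))
    expect_true(all(ct[[m]][hub] > ct[[m]][!hub]))
  topo <- compositeTopologyScore(ct)
  expect_equal(topo$composite_score[hub], 100)
  expect_true(all(topo$composite_score[hub] > topo$composite_score[!hub]))
})

test_that("disconnected graphs are scored within components", {
  # an edge plus an isolated triangle plus a singleton-free pair
  net <- makeNetwork(c("A", "C", "D", "E"), c("B", "D", "E", "C"))
  ct <- computeCentralities(net)
  ab <- ct[ct$gene_id %in% c("A", "B"), ]
  expect_equal(ab$closeness, c(1, 1))
  expect_equal(ab$eigenvector, rep(1 / sqrt(2), 2))
  cde <- ct[ct$gene_id %in% c("C", "D", "E"), ]
  expect_equal(cde$eigenvector, rep(1 / sqrt(3), 3))
})

test_that("centralities agree with exhaustive path enumeration on random graphs", {
  set.seed(57)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    adj <- randomConnectedAdj(n, runif(1, 0.3, 0.7))
    ids <- sprintf("n%02d", seq_len(n))
    got <- computeCentralities(adjToNetwork(adj, ids))
    got <- got[match(ids, got$gene_id), ]
    want <- bruteCentralities(adj)
    expect_equal(got$degree, as.integer(want$degree))
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-10)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-10)
    expect_equal(got$radiality, want$radiality, tolerance = 1e-10)
    expect_equal(got$stress, want$stress)
    expect_equal(got$eigenvector, want$eigenvector, tolerance = 1e-8)
  }
})

test_that("composite scores are equivariant under node relabeling", {
  set.seed(71)
  adj <- randomConnectedAdj(7, 0.4)
  ids <- sprintf("n%02d", 1:7)
  perm <- sample(7)
  a <- compositeTopologyScore(computeCentralities(adjToNetwork(adj, ids)))
  b <- compositeTopologyScore(computeCentralities(
    adjToNetwork(adj[perm, perm], ids[perm])))
  a <- a[order(a$gene_id), ]
  b <- b[order(b$gene_id), ]
  expect_equal(a$composite_score, b$composite_score)
  # vertex-transitive graph: all composites equal
  k5 <- completeGraphNetwork(sprintf("v%d", 1:5))
  topo <- compositeTopologyScore(computeCentralities(k5))
  expect_length(unique(topo$composite_score), 1L)
})

test_that("round-2 selection is inclusive at the mark and nested across marks", {
  sc <- data.frame(gene_id = c("a", "b", "c"),
                   composite_score = c(60, 50, 40), stringsAsFactors = FALSE)
  expect_setequal(selectRound2(sc, 50), c("a", "b"))
  expect_setequal(selectRound2(sc, 0), c("a", "b", "c"))
  expect_setequal(selectRound2(sc, 50, rule = "le"), c("b", "c"))

  set.seed(83)
  adj <- randomConnectedAdj(12, 0.3)
  topo <- compositeTopologyScore(computeCentralities(adjToNetwork(adj)))
  expect_true(all(selectRound2(topo, 80) %in% selectRound2(topo, 50)))
})
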