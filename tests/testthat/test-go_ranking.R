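test_that("GO term scores follow the enrichment-ratio definition", {
  regulated <- sprintf("r%02d", 1:50)
  ann <- annotationSetFromList(list("GO:T1" = regulated[1:5]), "BP",
                               termBg = c("GO:T1" = 100L), popBg = 10000L)
  ts <- scoreTerms(regulated, ann, "BP")
  expect_equal(ts$observed, 5L)
  expect_equal(ts$input_count, 50L)
  expect_equal(ts$go_score, 10)  # (5/50) / (100/10000)

  # saturation: observed = input and term background = population
  reg <- sprintf("s%02d", 1:10)
  annSat <- annotationSetFromList(list("GO:T2" = reg), "CC",
                                  termBg = c("GO:T2" = 1000L), popBg = 1000L)
  expect_equal(scoreTerms(reg, annSat, "CC")$go_score, 1)

  # scale invariance: multiplying all four counts leaves the score unchanged
  annBig <- annotationSetFromList(list("GO:T1" = regulated[1:5]), "BP",
                                  termBg = c("GO:T1" = 300L), popBg = 30000L)
  expect_equal(scoreTerms(regulated, ann, "BP")$go_score,
               scoreTerms(regulated, annBig, "BP")$go_score)
})

test_that("term and gene scores match an independent brute-force oracle", {
  syn <- generateSynthetic(syntheticSpec(nGenes = 150L, nTerms = 8L,
                                         seed = 19L))
  regulated <- syn$truth@upGenes
  ann <- as.data.frame(syn$annotations)
  for (ns in c("BP", "CC", "MF")) {
    ts <- scoreTerms(regulated, syn$annotations, ns)
    sub <- ann[ann$namespace == ns, ]
    for (i in seq_len(nrow(ts))) {
      genesOfTerm <- sub$gene_id[sub$term_id == ts$term_id[i]]
      obs <- length(intersect(genesOfTerm, regulated))
      tb <- sub$term_background_count[sub$term_id == ts$term_id[i]][1]
      pb <- sub$population_background_count[1]
      expect_equal(ts$observed[i], obs)
      expect_equal(ts$go_score[i],
                   (obs / length(regulated)) / (tb / pb))
    }
    # gene scores: explicit gene-by-term double loop
    sc <- scoreGenes(ts, syn$annotations, regulated)
    adm <- ts[ts$admitted, ]
    for (g in names(sc)) {
      terms <- sub$term_id[sub$gene_id == g]
      expect_equal(unname(sc[g]),
                   sum(adm$go_score[adm$term_id %in% terms]))
    }
  }
})

test_that("genes annotated only to non-admitted terms score zero", {
  ts <- data.frame(term_id = c("GO:A", "GO:B", "GO:C"), namespace = "BP",
                   go_score = c(2, 3, 50), admitted = c(TRUE, TRUE, FALSE),
                   stringsAsFactors = FALSE)
  ann <- annotationSetFromList(
    list("GO:A" = c("g1"), "GO:B" = c("g1"), "GO:C" = c("g2")), "BP",
    termBg = c("GO:A" = 10L, "GO:B" = 10L, "GO:C" = 10L), popBg = 100L)
  sc <- scoreGenes(ts, ann, c("g1", "g2"))
  expect_equal(unname(sc["g1"]), 5)  # 2 + 3 over admitted terms
  expect_equal(unname(sc["g2"]), 0)
})

test_that("percentile ranks are inclusive empirical CDF percentages", {
  expect_equal(unname(percentileRank(c(a = 1, b = 2, c = 3))),
               c(100 / 3, 200 / 3, 100))
  expect_equal(unname(percentileRank(c(only = 5))), 100)
  expect_equal(unname(percentileRank(c(a = 2, b = 2, c = 2))),
               c(100, 100, 100))
  expect_error(percentileRank(numeric(0)), "empty")
  # invariance under strictly increasing transforms
  set.seed(33)
  x <- rnorm(40)
  expect_equal(percentileRank(x), percentileRank(exp(x)))
  expect_equal(percentileRank(x), percentileRank(2 * x + 7))
})

test_that("average percentile spans only the namespaces a gene occupies", {
  # b occupies BP only; a occupies BP and CC
  ann <- annotationSetFromList(list("GO:P" = c("a", "b"), "GO:Q" = c("b")),
                               "BP", popBg = 100L)
  cc <- annotationSetFromList(list("GO:R" = c("a")), "CC", popBg = 100L)
  both <- new("AnnotationSet",
              annotations = rbind(as.data.frame(ann), as.data.frame(cc)))
  rt <- rankGenes(c("a", "b"), both, admissionP = 1)
  tab <- as.data.frame(rt)
  a <- tab[tab$gene_id == "a", ]
  b <- tab[tab$gene_id == "b", ]
  expect_equal(a$average_percentile,
               mean(c(a$percentile_BP, a$percentile_CC)))
  expect_true(is.na(b$percentile_CC))
  expect_equal(b$average_percentile, b$percentile_BP)  # BP-only gene
})

test_that("rank-table percentiles match an independent CDF recomputation", {
  syn <- generateSynthetic(syntheticSpec(nGenes = 120L, nTerms = 6L,
                                         seed = 29L))
  rt <- rankGenes(syn$truth@upGenes, syn$annotations)
  tab <- as.data.frame(rt)
  for (ns in rt@namespaces) {
    sc <- tab[[paste0("score_", ns)]]
    pc <- tab[[paste0("percentile_", ns)]]
    keep <- !is.na(sc)
    oracle <- vapply(sc[keep],
                     function(s) 100 * mean(sc[keep] <= s), numeric(1))
    expect_equal(pc[keep], oracle)
  }
  avgOracle <- rowMeans(
    as.matrix(tab[paste0("percentile_", rt@namespaces)]), na.rm = TRUE)
  expect_equal(tab$average_percentile, unname(avgOracle))
})

test_that("round-1 screening is inclusive at the cutoff and antitone in it", {
  tab <- data.frame(gene_id = c("a", "b", "c"),
                    average_percentile = c(85, 80, 79),
                    selected_round1 = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  rt <- new("GeneRankTable", table = tab, namespaces = "BP", cutoff = 80)
  expect_setequal(screenRound1(rt, 80), c("a", "b"))
  expect_setequal(screenRound1(rt, 0), c("a", "b", "c"))

  syn <- generateSynthetic(syntheticSpec(nGenes = 150L, seed = 37L))
  rt <- rankGenes(syn$truth@upGenes, syn$annotations)
  s80 <- screenRound1(rt, 80)
  s90 <- screenRound1(rt, 90)
  expect_true(all(s90 %in% s80))
})
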