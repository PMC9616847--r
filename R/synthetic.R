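## Synthetic study generator: a DEG universe with known regulated sets, an
## interaction network with dense planted modules over a sparse background,
## and flat GO annotations with terms deliberately enriched in the
## up-regulated set. All randomness flows from the spec seed, so identical
## specs give identical artifacts.

#' Build a synthetic study specification
#'
#' Defaults describe a mid-sized desk study: a 1000-gene universe with 20%
#' up- and 25% down-regulated genes (roughly the up:down balance seen in
#' preserved-leaf transcriptomes), regulated fold changes of
#' `2 + |Normal(0.9, 0.5)|` on the log2 scale so the mean regulated
#' magnitude sits near 2.9, significant FDRs uniform on (0, 0.05), two
#' planted dense modules (sizes 10 and 6 at within-module edge probability
#' 0.9) over a 0.02 background, 20 background GO terms per namespace, and
#' one planted BP term of 100 genes drawing half its members from the
#' up-regulated set.
#'
#' @param nGenes gene-universe size.
#' @param fracUp,fracDown regulated fractions (sum <= 1).
#' @param lfcLocation,lfcScale location/scale of the half-normal magnitude
#'   added to the fold-change floor of 2.
#' @param fdrSigMax regulated genes draw FDR uniformly on (0, fdrSigMax).
#' @param modules list of `list(size =, pIn =)` planted modules (disjoint,
#'   placed on up-regulated genes when enough are available).
#' @param pOut background edge probability (< every module `pIn`).
#' @param nTerms background GO terms per namespace.
#' @param plantedTerms list of `list(namespace =, size =, fracUp =)`;
#'   default: one BP term covering 10% of the universe with half its
#'   members up-regulated.
#' @param seed integer RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nGenes = 1000L, fracUp = 0.2, fracDown = 0.25,
                          lfcLocation = 0.9, lfcScale = 0.5,
                          fdrSigMax = 0.05,
                          modules = list(list(size = 10L, pIn = 0.9),
                                         list(size = 6L, pIn = 0.9)),
                          pOut = 0.02, nTerms = 20L,
                          plantedTerms = NULL,
                          seed = 1L) {
  if (is.null(plantedTerms))
    plantedTerms <- list(list(namespace = "BP",
                              size = max(5L, as.integer(round(0.1 * nGenes))),
                              fracUp = 0.5))
  new("SyntheticSpec", nGenes = as.integer(nGenes), fracUp = fracUp,
      fracDown = fracDown, lfcLocation = lfcLocation, lfcScale = lfcScale,
      fdrSigMax = fdrSigMax, modules = modules, pOut = pOut,
      nTerms = as.integer(nTerms), plantedTerms = plantedTerms,
      seed = as.integer(seed))
}

## run expr under a deterministic seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hasSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic study
#'
#' Deterministic in the spec seed. By construction, regulated genes satisfy
#' `|log2fc| >= 2` and `fdr < 0.05`, non-regulated genes have
#' `|log2fc| < 2`, each planted module's internal edges are Bernoulli(pIn)
#' (density pIn in expectation) over a Bernoulli(pOut) background, and each
#' planted term draws its stated fraction of members from the up-regulated
#' set. Term background counts equal the true generated term sizes and the
#' population background equals the gene universe, so enrichment tests on
#' generated data are exactly hypergeometric under permutation.
#'
#' @param spec a [SyntheticSpec-class].
#' @return a list with elements `deg` ([DEGTable-class], unclassified),
#'   `network` ([PPINetwork-class]), `annotations` ([AnnotationSet-class]),
#'   `truth` ([GroundTruth-class]).
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  withSeed(spec@seed, {
    n <- spec@nGenes
    genes <- sprintf("g%05d", seq_len(n))
    nUp <- round(spec@fracUp * n)
    nDown <- round(spec@fracDown * n)
    shuffled <- sample(genes)
    up <- sort(shuffled[seq_len(nUp)])
    down <- sort(shuffled[nUp + seq_len(nDown)])
    rest <- setdiff(genes, c(up, down))

    deg <- data.frame(gene_id = genes, log2fc = 0, fdr = 1,
                      stringsAsFactors = FALSE)
    rownames(deg) <- genes
    deg[up, "log2fc"] <- 2 + abs(rnorm(nUp, spec@lfcLocation, spec@lfcScale))
    deg[down, "log2fc"] <- -(2 + abs(rnorm(nDown, spec@lfcLocation,
                                           spec@lfcScale)))
    deg[c(up, down), "fdr"] <- runif(nUp + nDown, 0, spec@fdrSigMax)
    deg[rest, "log2fc"] <- runif(length(rest), -1.95, 1.95)
    deg[rest, "fdr"] <- runif(length(rest))
    rownames(deg) <- NULL

    ## network: planted modules preferentially on up-regulated genes
    moduleSizes <- vapply(spec@modules, function(m) m$size, numeric(1))
    pool <- if (sum(moduleSizes) <= length(up)) up else genes
    moduleNodes <- list()
    taken <- character(0)
    for (m in spec@modules) {
      pick <- sort(sample(setdiff(pool, taken), m$size))
      moduleNodes[[length(moduleNodes) + 1L]] <- pick
      taken <- c(taken, pick)
    }
    pairs <- utils::combn(genes, 2L)
    p <- rep(spec@pOut, ncol(pairs))
    for (i in seq_along(moduleNodes)) {
      inA <- pairs[1L, ] %in% moduleNodes[[i]]
      inB <- pairs[2L, ] %in% moduleNodes[[i]]
      p[inA & inB] <- spec@modules[[i]]$pIn
    }
    keep <- runif(ncol(pairs)) < p
    score <- round(runif(sum(keep), 0.4, 0.999), 3)
    network <- edgesToNetwork(pairs[1L, keep], pairs[2L, keep], score)

    ## annotations: background terms plus planted enriched terms
    rows <- list()
    for (ns in GO_NAMESPACES) {
      for (i in seq_len(spec@nTerms)) {
        size <- sample(10:80, 1L)
        members <- sample(genes, min(size, n))
        rows[[length(rows) + 1L]] <- data.frame(
          term_id = sprintf("GO:%s%04d", ns, i), namespace = ns,
          gene_id = members, stringsAsFactors = FALSE)
      }
    }
    plantedIds <- character(0)
    for (i in seq_along(spec@plantedTerms)) {
      t <- spec@plantedTerms[[i]]
      id <- sprintf("GO:%s9%03d", t$namespace, i)
      kUp <- min(round(t$fracUp * t$size), length(up))
      others <- sample(setdiff(genes, up), t$size - kUp)
      members <- c(sample(up, kUp), others)
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = id, namespace = t$namespace, gene_id = members,
        stringsAsFactors = FALSE)
      plantedIds <- c(plantedIds, id)
    }
    ann <- do.call(rbind, rows)
    sizes <- table(ann$term_id)
    ann$term_background_count <- as.integer(sizes[ann$term_id])
    ann$population_background_count <- n
    ann <- ann[order(ann$namespace, ann$term_id, ann$gene_id), ,
               drop = FALSE]
    rownames(ann) <- NULL

    list(deg = new("DEGTable", table = deg),
         network = network,
         annotations = new("AnnotationSet", annotations = ann),
         truth = new("GroundTruth", upGenes = up, downGenes = down,
                     modules = moduleNodes, plantedTermIds = plantedIds))
  })
}
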