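## Orchestration: classify -> round-1 GO ranking -> round-2 topology ->
## complex detection -> enrichment -> direction comparison. Up- and
## down-regulated branches run independently on the shared network and
## annotations and meet only in the final comparison.

#' Assemble a pipeline run configuration
#'
#' Inputs may be given as in-memory objects or as TSV paths (read with the
#' package readers). Threshold defaults are the pipeline's standard
#' settings: fold-change floor 2, FDR < 0.05, term-admission p 0.05,
#' round-1 percentile cutoff 80, round-2 mark 50 (selecting at or above),
#' enrichment p <= 0.05 uncorrected.
#'
#' @param deg a [DEGTable-class] or path.
#' @param network a [PPINetwork-class] or path.
#' @param annotations an [AnnotationSet-class] or path.
#' @param lfcMin,fdrMax regulation-call thresholds.
#' @param admissionP round-1 term-admission p-value.
#' @param round1Cutoff round-1 average-percentile cutoff.
#' @param round2Mark,round2Rule round-2 composite mark and direction
#'   (`"ge"` keeps scores at or above the mark).
#' @param enrichCutoff,correction enrichment significance settings.
#' @param mcode an [MCODEParams-class].
#' @param scoreMin minimum combined score when reading an edge list.
#' @param outDir optional output directory for stage TSV/JSON artifacts.
#' @return a `RunConfig` list (class `"deg_run_config"`).
#' @export
runConfig <- function(deg, network, annotations,
                      lfcMin = 2, fdrMax = 0.05, admissionP = 0.05,
                      round1Cutoff = 80, round2Mark = 50,
                      round2Rule = c("ge", "le"), enrichCutoff = 0.05,
                      correction = c("none", "BH"), mcode = mcodeParams(),
                      scoreMin = 0, outDir = NULL) {
  structure(list(deg = deg, network = network, annotations = annotations,
                 lfcMin = lfcMin, fdrMax = fdrMax, admissionP = admissionP,
                 round1Cutoff = round1Cutoff, round2Mark = round2Mark,
                 round2Rule = match.arg(round2Rule),
                 enrichCutoff = enrichCutoff,
                 correction = match.arg(correction), mcode = mcode,
                 scoreMin = scoreMin, outDir = outDir),
            class = "deg_run_config")
}

resolveInput <- function(x, reader, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x))
      stop(sprintf("%s input file not found: %s", what, x), call. = FALSE)
    return(reader(x))
  }
  x
}

#' Run the full two-round prioritization pipeline
#'
#' Stages per direction (up, down): regulation calls; round-1 GO ratio
#' scoring, gene-score summation, percentile ranking and screening; the
#' induced subnetwork of round-1 survivors; six-centrality composite
#' scoring and the round-2 mark; complex detection on the round-2
#' subnetwork; hypergeometric enrichment of the round-2 survivors. The two
#' directions meet only in the shared/specific term comparison. Identical
#' configuration and inputs give identical reports.
#'
#' @param config a configuration from [runConfig()].
#' @return a `RunReport` list (class `"deg_run_report"`): per-direction
#'   stage outputs and counts, the direction comparison, and the thresholds
#'   used. If `config$outDir` is set, stage tables are written as TSV and
#'   the report summary as JSON.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "deg_run_config"))
  deg <- resolveInput(config$deg, readDEGTable, "DEG table")
  network <- resolveInput(config$network,
                          function(p) readEdgeList(p, config$scoreMin),
                          "edge list")
  annotations <- resolveInput(config$annotations, readAnnotations,
                              "annotation table")
  stopifnot(is(deg, "DEGTable"), is(network, "PPINetwork"),
            is(annotations, "AnnotationSet"))

  classified <- classifyDEG(deg, lfcMin = config$lfcMin,
                            fdrMax = config$fdrMax)
  logStage("classify", nrow(classified@table),
           sum(classified@table$call != "not_significant"))

  directions <- list()
  for (dir in c("up", "down")) {
    regulated <- regulatedGenes(classified, dir)
    branch <- list(direction = dir, n_regulated = length(regulated))
    if (length(regulated) == 0L) {
      branch <- c(branch, emptyBranch())
      directions[[dir]] <- branch
      next
    }
    rank1 <- rankGenes(regulated, annotations,
                       admissionP = config$admissionP,
                       cutoff = config$round1Cutoff)
    survivors1 <- screenRound1(rank1, cutoff = config$round1Cutoff)
    logStage(paste0("round1-", dir), branch$n_regulated, length(survivors1))

    sub <- suppressWarnings(inducedSubnetwork(network, survivors1))
    cent <- computeCentralities(sub)
    topo <- compositeTopologyScore(cent)
    survivors2 <- if (nrow(topo) > 0L)
      selectRound2(topo, mark = config$round2Mark, rule = config$round2Rule)
    else character(0)
    logStage(paste0("round2-", dir), nNodes(sub), length(survivors2))

    clusters <- findComplexes(sub, config$mcode)

    enrichment <- if (length(survivors2) > 0L)
      enrichTerms(survivors2, annotations, cutoff = config$enrichCutoff,
                  correction = config$correction)
    else emptyBranch()$enrichment
    logStage(paste0("enrich-", dir), length(survivors2),
             sum(enrichment$significant))

    directions[[dir]] <- c(branch, list(
      rank_table = rank1, round1_selected = survivors1,
      subnetwork_nodes = nNodes(sub), subnetwork_edges = nEdges(sub),
      topology = topo, round2_selected = survivors2,
      clusters = clusters, enrichment = enrichment,
      n_round1 = length(survivors1), n_round2 = length(survivors2),
      n_clusters = length(clusters),
      n_enriched = sum(enrichment$significant)))
  }

  comparison <- compareDirections(
    directions$up$enrichment$term_id[directions$up$enrichment$significant],
    directions$down$enrichment$term_id[directions$down$enrichment$significant])

  report <- structure(list(
    n_genes = nrow(classified@table),
    calls = table(factor(classified@table$call, levels = REGULATION_CALLS)),
    up = directions$up, down = directions$down,
    comparison = comparison,
    n_shared = length(comparison$shared),
    thresholds = config[c("lfcMin", "fdrMax", "admissionP", "round1Cutoff",
                          "round2Mark", "round2Rule", "enrichCutoff",
                          "correction")]),
    class = "deg_run_report")

  if (!is.null(config$outDir)) writeRunArtifacts(report, config$outDir)
  report
}

emptyBranch <- function() {
  list(rank_table = NULL, round1_selected = character(0),
       subnetwork_nodes = 0L, subnetwork_edges = 0L,
       topology = NULL, round2_selected = character(0),
       clusters = new("ClusterSet", clusters = list()),
       enrichment = data.frame(term_id = character(0),
                               namespace = character(0),
                               observed = integer(0), expected = numeric(0),
                               p_value = numeric(0), adjusted_p = numeric(0),
                               significant = logical(0)),
       n_round1 = 0L, n_round2 = 0L, n_clusters = 0L, n_enriched = 0L)
}

logStage <- function(stage, nIn, nOut) {
  message(sprintf("[%s] in=%d out=%d", stage, nIn, nOut))
}

## stage tables as TSV, summary as canonical JSON
writeRunArtifacts <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (dir in c("up", "down")) {
    b <- report[[dir]]
    if (!is.null(b$rank_table))
      writeTsv(as.data.frame(b$rank_table),
               file.path(outDir, sprintf("rank_round1_%s.tsv", dir)))
    if (!is.null(b$topology) && nrow(b$topology) > 0L)
      writeTsv(b$topology, file.path(outDir, sprintf("topology_%s.tsv", dir)))
    writeTsv(as.data.frame(b$clusters),
             file.path(outDir, sprintf("clusters_%s.tsv", dir)))
    writeTsv(b$enrichment, file.path(outDir, sprintf("enrichment_%s.tsv", dir)))
  }
  summary <- list(
    n_genes = report$n_genes,
    calls = as.list(setNames(as.integer(report$calls), names(report$calls))),
    up = branchSummary(report$up), down = branchSummary(report$down),
    comparison = lapply(report$comparison, as.character),
    thresholds = report$thresholds)
  jsonlite::write_json(summary, file.path(outDir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

branchSummary <- function(b) {
  cl <- clusterList(b$clusters)
  list(n_regulated = b$n_regulated, n_round1 = b$n_round1,
       subnetwork_nodes = b$subnetwork_nodes,
       subnetwork_edges = b$subnetwork_edges,
       n_round2 = b$n_round2, n_enriched = b$n_enriched,
       clusters = lapply(cl, function(x)
         list(n = x$n, e = x$e, density = x$density, score = x$score,
              seed = x$seed)))
}

#' @export
print.deg_run_report <- function(x, ...) {
  cat("Two-round prioritization report\n")
  cat(sprintf("  genes: %d (up %d, down %d)\n", x$n_genes,
              x$calls[["up"]], x$calls[["down"]]))
  for (dir in c("up", "down")) {
    b <- x[[dir]]
    cat(sprintf(
      "  %s: round1 %d -> subnetwork %d nodes/%d edges -> round2 %d; %d cluster(s); %d enriched term(s)\n",
      dir, b$n_round1, b$subnetwork_nodes, b$subnetwork_edges, b$n_round2,
      b$n_clusters, b$n_enriched))
  }
  cat(sprintf("  shared enriched terms: %d (up-specific %d, down-specific %d)\n",
              length(x$comparison$shared), length(x$comparison$up_specific),
              length(x$comparison$down_specific)))
  invisible(x)
}
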