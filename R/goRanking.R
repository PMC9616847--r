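## Round-1 screening: GO ratio scoring -> per-gene summation -> percentile
## ranking per namespace -> average percentile -> top-band selection.

#' Score GO terms of a regulated gene set by enrichment ratio
#'
#' For every term in `namespace` containing at least one regulated gene, the
#' GO score is the fold-enrichment ratio
#' `(observed / input) / (term_background / population_background)`:
#' observed gene count over the regulated input count, divided by the term's
#' background share of the annotation population. Each term also receives an
#' upper-tail hypergeometric p-value, and terms above the admission threshold
#' are flagged non-admitted: they do not contribute to gene scoring.
#'
#' @param regulated character vector of regulated gene ids (non-empty).
#' @param annotations an [AnnotationSet-class].
#' @param namespace one of `"BP"`, `"CC"`, `"MF"`.
#' @param admissionP p-value threshold for a term to enter gene scoring
#'   (default 0.05).
#' @return a `data.frame` with `term_id`, `namespace`, `observed`,
#'   `input_count`, `term_background_count`, `population_background_count`,
#'   `go_score`, `p_value`, `admitted`.
#' @export
scoreTerms <- function(regulated, annotations, namespace, admissionP = 0.05) {
  stopifnot(is(annotations, "AnnotationSet"))
  namespace <- match.arg(namespace, GO_NAMESPACES)
  regulated <- unique(regulated)
  if (length(regulated) == 0L)
    stop("regulated gene set is empty", call. = FALSE)
  ann <- annotations@annotations
  ann <- ann[ann$namespace == namespace, , drop = FALSE]
  hit <- ann[ann$gene_id %in% regulated, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(data.frame(term_id = character(0), namespace = character(0),
                      observed = integer(0), input_count = integer(0),
                      term_background_count = integer(0),
                      population_background_count = integer(0),
                      go_score = numeric(0), p_value = numeric(0),
                      admitted = logical(0)))
  }
  obs <- tapply(hit$gene_id, hit$term_id, function(g) length(unique(g)))
  meta <- hit[!duplicated(hit$term_id), , drop = FALSE]
  obs <- as.integer(obs[meta$term_id])
  input <- length(regulated)
  tb <- meta$term_background_count
  pb <- meta$population_background_count
  if (any(obs > tb))
    stop("observed memberships exceed the stated term background count",
         call. = FALSE)
  res <- data.frame(
    term_id = meta$term_id, namespace = namespace, observed = obs,
    input_count = input, term_background_count = tb,
    population_background_count = pb,
    go_score = (obs / input) / (tb / pb),
    p_value = hypergeomUpper(obs, pmin(input, pb), tb, pb),
    stringsAsFactors = FALSE)
  res$admitted <- res$p_value <= admissionP
  res[order(res$term_id), , drop = FALSE]
}

#' Sum admitted term scores per gene
#'
#' A gene's namespace score is the sum of the GO scores of the admitted
#' terms annotating it; genes annotated only to non-admitted terms score 0.
#' Only regulated genes annotated in the namespace are scored.
#'
#' @param termScores output of [scoreTerms()] (one namespace).
#' @param annotations an [AnnotationSet-class].
#' @param regulated character vector of regulated gene ids.
#' @return named numeric vector of gene scores.
#' @export
scoreGenes <- function(termScores, annotations, regulated) {
  stopifnot(is(annotations, "AnnotationSet"))
  if (length(unique(termScores$namespace)) > 1L)
    stop("termScores must come from a single namespace", call. = FALSE)
  regulated <- unique(regulated)
  ns <- unique(termScores$namespace)
  ann <- annotations@annotations
  if (length(ns) == 1L) ann <- ann[ann$namespace == ns, , drop = FALSE]
  ann <- ann[ann$gene_id %in% regulated, , drop = FALSE]
  genes <- sort(unique(ann$gene_id))
  scores <- setNames(numeric(length(genes)), genes)
  adm <- termScores[termScores$admitted, , drop = FALSE]
  if (nrow(adm) > 0L) {
    contrib <- ann[ann$term_id %in% adm$term_id, , drop = FALSE]
    termScore <- setNames(adm$go_score, adm$term_id)
    agg <- tapply(termScore[contrib$term_id], contrib$gene_id, sum)
    scores[names(agg)] <- as.numeric(agg)
  }
  scores
}

#' Percentile rank of scores
#'
#' Inclusive empirical-CDF percentiles: `100 * #(score <= score(g)) / N`.
#' Tied scores share a percentile and the maximum element(s) get 100,
#' so a "80% and above" screen always retains the top of the ranking. The
#' rank is invariant under any strictly increasing transform of the scores.
#'
#' @param scores named numeric vector (non-empty).
#' @return named numeric vector of percentiles in (0, 100\].
#' @export
#' @examples
#' percentileRank(c(a = 1, b = 2, c = 3))
percentileRank <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  100 * rank(scores, ties.method = "max") / length(scores)
}

#' Rank regulated genes by averaged GO percentile
#'
#' Runs [scoreTerms()] and [scoreGenes()] in each namespace present in the
#' annotations, percentile-ranks the per-namespace gene scores, and averages
#' the percentiles over the namespaces in which each gene is annotated
#' (compartment-specific genes are averaged over the namespaces they occupy,
#' not penalized with zeros). Genes absent from every namespace are excluded
#' from the table.
#'
#' @param regulated character vector of regulated gene ids.
#' @param annotations an [AnnotationSet-class].
#' @param admissionP term-admission p-value threshold (default 0.05).
#' @param cutoff round-1 selection cutoff on the average percentile
#'   (default 80; genes at or above it are flagged `selected_round1`).
#' @return a [GeneRankTable-class].
#' @export
rankGenes <- function(regulated, annotations, admissionP = 0.05, cutoff = 80) {
  stopifnot(is(annotations, "AnnotationSet"))
  regulated <- unique(regulated)
  namespaces <- intersect(GO_NAMESPACES,
                          unique(annotations@annotations$namespace))
  perNs <- list()
  for (ns in namespaces) {
    ts <- scoreTerms(regulated, annotations, ns, admissionP = admissionP)
    if (nrow(ts) == 0L) next
    sc <- scoreGenes(ts, annotations, regulated)
    if (length(sc) == 0L) next
    perNs[[ns]] <- data.frame(gene_id = names(sc), score = as.numeric(sc),
                              percentile = as.numeric(percentileRank(sc)),
                              stringsAsFactors = FALSE)
  }
  if (length(perNs) == 0L) {
    tab <- data.frame(gene_id = character(0), average_percentile = numeric(0),
                      selected_round1 = logical(0))
    return(new("GeneRankTable", table = tab, namespaces = character(0),
               cutoff = cutoff))
  }
  genes <- sort(unique(unlist(lapply(perNs, `[[`, "gene_id"))))
  tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  pctMat <- matrix(NA_real_, nrow = length(genes), ncol = length(perNs),
                   dimnames = list(genes, names(perNs)))
  for (ns in names(perNs)) {
    d <- perNs[[ns]]
    tab[[paste0("score_", ns)]] <- d$score[match(genes, d$gene_id)]
    tab[[paste0("percentile_", ns)]] <- d$percentile[match(genes, d$gene_id)]
    pctMat[d$gene_id, ns] <- d$percentile
  }
  tab$average_percentile <- rowMeans(pctMat, na.rm = TRUE)
  tab$selected_round1 <- tab$average_percentile >= cutoff
  new("GeneRankTable", table = tab, namespaces = names(perNs), cutoff = cutoff)
}

#' Round-1 selection: top percentile band
#'
#' @param rankTable a [GeneRankTable-class].
#' @param cutoff inclusive average-percentile cutoff (default 80).
#' @return character vector of selected gene ids.
#' @export
screenRound1 <- function(rankTable, cutoff = 80) {
  stopifnot(is(rankTable, "GeneRankTable"))
  tab <- rankTable@table
  sort(tab$gene_id[tab$average_percentile >= cutoff])
}
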