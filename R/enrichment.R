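#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing at least `obs` annotated genes when
#' `draws` genes are sampled without replacement from a population of `pop`
#' genes of which `successesInPop` carry the annotation:
#' `P(X >= obs)` with `X ~ Hypergeometric(pop, successesInPop, draws)`.
#'
#' @param obs observed count (integer >= 0).
#' @param draws size of the drawn gene set.
#' @param successesInPop annotated genes in the population.
#' @param pop population size.
#' @return upper-tail p-value in \[0, 1\]. Vectorized over all arguments.
#' @export
#' @examples
#' hypergeomUpper(2, 2, 2, 5)  # 0.1
hypergeomUpper <- function(obs, draws, successesInPop, pop) {
  if (any(obs < 0) || any(draws < 0) || any(successesInPop < 0) || any(pop < 1))
    stop("counts must be non-negative and pop >= 1", call. = FALSE)
  if (any(draws > pop) || any(successesInPop > pop))
    stop("draws and successesInPop must not exceed pop", call. = FALSE)
  if (any(obs > pmin(draws, successesInPop)))
    stop("obs must not exceed min(draws, successesInPop)", call. = FALSE)
  phyper(obs - 1, successesInPop, pop - successesInPop, draws,
         lower.tail = FALSE)
}

#' Hypergeometric over-representation test on a gene set
#'
#' For every annotated term with at least one observed gene, tests whether
#' the term is over-represented in `genes` relative to the annotation
#' background, in the style of a BiNGO run: the population is the term's
#' stated `population_background_count` and the term's successes are its
#' `term_background_count`. Significance is decided at the raw p-value by
#' default; Benjamini-Hochberg adjustment is available behind `correction`.
#'
#' @param genes character vector of gene ids (non-empty).
#' @param annotations an [AnnotationSet-class].
#' @param cutoff significance cutoff on the chosen p column (default 0.05).
#' @param correction `"none"` (raw p, the default) or `"BH"`.
#' @param namespace optional restriction to one of BP/CC/MF.
#' @return a `data.frame` with one row per term (observed >= 1): `term_id`,
#'   `namespace`, `observed`, `expected`, `p_value`, `adjusted_p`,
#'   `significant`; sorted by p-value then term id.
#' @export
enrichTerms <- function(genes, annotations, cutoff = 0.05,
                        correction = c("none", "BH"), namespace = NULL) {
  correction <- match.arg(correction)
  stopifnot(is(annotations, "AnnotationSet"))
  if (length(genes) == 0L) stop("gene set is empty", call. = FALSE)
  genes <- unique(genes)
  ann <- annotations@annotations
  if (!is.null(namespace)) {
    namespace <- match.arg(namespace, GO_NAMESPACES)
    ann <- ann[ann$namespace == namespace, , drop = FALSE]
  }
  hit <- ann[ann$gene_id %in% genes, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(data.frame(term_id = character(0), namespace = character(0),
                      observed = integer(0), expected = numeric(0),
                      p_value = numeric(0), adjusted_p = numeric(0),
                      significant = logical(0)))
  }
  key <- paste(hit$term_id, hit$namespace, sep = "\r")
  obs <- tapply(hit$gene_id, key, function(g) length(unique(g)))
  meta <- hit[!duplicated(key), , drop = FALSE]
  metaKey <- paste(meta$term_id, meta$namespace, sep = "\r")
  obs <- as.integer(obs[metaKey])
  draws <- length(genes)
  tb <- meta$term_background_count
  pb <- meta$population_background_count
  if (any(obs > tb))
    stop("observed memberships exceed the stated term background count",
         call. = FALSE)
  p <- hypergeomUpper(obs, pmin(draws, pb), tb, pb)
  res <- data.frame(term_id = meta$term_id, namespace = meta$namespace,
                    observed = obs, expected = draws * tb / pb,
                    p_value = p, adjusted_p = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  pcol <- if (correction == "BH") res$adjusted_p else res$p_value
  res$significant <- pcol <= cutoff
  res[order(res$p_value, res$term_id), , drop = FALSE]
}

#' Shared and direction-specific enriched processes
#'
#' Exact set comparison of the terms enriched in the up- and down-regulated
#' selections.
#'
#' @param upTerms,downTerms character vectors of term ids.
#' @return a list with `shared`, `up_specific`, `down_specific` (sorted).
#' @export
compareDirections <- function(upTerms, downTerms) {
  upTerms <- unique(upTerms); downTerms <- unique(downTerms)
  list(shared = sort(intersect(upTerms, downTerms)),
       up_specific = sort(setdiff(upTerms, downTerms)),
       down_specific = sort(setdiff(downTerms, upTerms)))
}
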