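#' Relative quantity by the comparative Ct method
#'
#' Livak comparative threshold-cycle calculation:
#' `dCt_test = ctTargetTest - ctRefTest`,
#' `dCt_cal = ctTargetCal - ctRefCal`, `ddCt = dCt_test - dCt_cal`,
#' `RQ = 2^-ddCt`. Equal cycles everywhere give RQ = 1; a target that
#' amplifies two cycles earlier in the test sample (references equal) gives
#' RQ = 4.
#'
#' @param ctTargetTest,ctRefTest target and endogenous-reference Ct in the
#'   test sample (cycles).
#' @param ctTargetCal,ctRefCal the same in the calibrator sample.
#' @return relative quantity (positive). Vectorized.
#' @export
#' @examples
#' relativeQuantity(20, 18, 22, 18)  # 4
relativeQuantity <- function(ctTargetTest, ctRefTest, ctTargetCal, ctRefCal) {
  vals <- c(ctTargetTest, ctRefTest, ctTargetCal, ctRefCal)
  if (any(!is.finite(vals)))
    stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ctTargetTest - ctRefTest) - (ctTargetCal - ctRefCal)
  2^(-ddct)
}

#' Relative quantification of a replicated Ct table
#'
#' Replicates are averaged on the Ct scale (a geometric mean on the quantity
#' scale, the standard instrument behaviour) before the comparative-Ct
#' calculation. The reported SD is the replicate SD of ddCt
#' (`sqrt(sd_test^2 + sd_cal^2)` of the per-replicate dCt values) mapped to
#' the RQ scale as `log(2) * RQ * sd_ddct`.
#'
#' @param ct a `data.frame` as returned by [readCtTable()]: columns
#'   `gene_id`, `condition` (`test`/`calibrator`), `replicate`,
#'   `ct_target`, `ct_reference`.
#' @return a `data.frame` with one row per gene: `gene_id`, `rq`, `rq_sd`,
#'   `ddct`, `n_test`, `n_calibrator`.
#' @export
qpcrQuantify <- function(ct) {
  needed <- c("gene_id", "condition", "replicate", "ct_target", "ct_reference")
  stopifnot(all(needed %in% names(ct)))
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)))
    stop("all Ct values must be finite", call. = FALSE)
  out <- lapply(split(ct, ct$gene_id), function(d) {
    test <- d[d$condition == "test", , drop = FALSE]
    cal <- d[d$condition == "calibrator", , drop = FALSE]
    if (nrow(test) == 0L || nrow(cal) == 0L)
      stop(sprintf("gene %s needs both test and calibrator measurements",
                   d$gene_id[1]), call. = FALSE)
    dctTest <- test$ct_target - test$ct_reference
    dctCal <- cal$ct_target - cal$ct_reference
    ddct <- mean(dctTest) - mean(dctCal)
    sdT <- if (nrow(test) > 1L) sd(dctTest) else 0
    sdC <- if (nrow(cal) > 1L) sd(dctCal) else 0
    sdD <- sqrt(sdT^2 + sdC^2)
    rq <- 2^(-ddct)
    data.frame(gene_id = d$gene_id[1], rq = rq,
               rq_sd = log(2) * rq * sdD, ddct = ddct,
               n_test = nrow(test), n_calibrator = nrow(cal),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$gene_id), , drop = FALSE]
}
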