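# Cross-layer statistics: methylation-expression coupling, promoter
# methylation scores, cross-promoter co-methylation, and tumor vs normal
# discrimination by AUROC.

#' Methylation-expression correlation
#'
#' Pearson or Spearman correlation between a per-sample methylation
#' value (single probe beta or promoter score) and matched expression,
#' pairing by sample name when both vectors are named; missing pairs are
#' dropped. Promoter hypomethylation with over-expression manifests as a
#' negative coefficient.
#'
#' @param meth,expr numeric vectors, ideally named by sample id.
#' @param method `"pearson"` or `"spearman"`.
#' @return list `r`, `p`, `n`, `method`.
#' @export
methylation_expression_correlation <- function(meth, expr,
                                               method = c("pearson",
                                                          "spearman")) {
  if (!is.null(names(meth)) && !is.null(names(expr))) {
    common <- intersect(names(meth), names(expr))
    meth <- meth[common]; expr <- expr[common]
  }
  cor_with_p(meth, expr, match.arg(method))
}

#' Per-sample promoter methylation score
#'
#' Mean beta (or median, configurable) over a stated probe interval;
#' missing values are excluded per sample.
#'
#' @param beta probes x samples matrix.
#' @param probes character vector of probe ids defining the interval.
#' @param map optional `cpg_map`; when given, `probes` are checked
#'   against it.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return named numeric vector (one score per sample) with the interval
#'   recorded in the `"interval"` attribute.
#' @export
promoter_score <- function(beta, probes, map = NULL,
                           aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(probes) == 0L) stop("empty probe interval")
  if (!is.null(map) && !all(probes %in% map$probe_id))
    stop("interval outside map: ",
         paste(setdiff(probes, map$probe_id), collapse = ", "))
  if (!all(probes %in% rownames(beta)))
    stop("interval outside beta matrix: ",
         paste(setdiff(probes, rownames(beta)), collapse = ", "))
  sub <- beta[probes, , drop = FALSE]
  score <- if (aggregate == "mean") colMeans(sub, na.rm = TRUE)
           else apply(sub, 2L, median, na.rm = TRUE)
  attr(score, "interval") <- probes
  score
}

#' Cross-promoter methylation correlation
#'
#' Correlation between two promoter scores over shared samples -- the
#' statistic behind "co-methylation" of two gene promoters.
#'
#' @param score_a,score_b outputs of [promoter_score()] (named vectors).
#' @inheritParams methylation_expression_correlation
#' @return list `r`, `p`, `n`, `method`.
#' @export
cross_promoter_correlation <- function(score_a, score_b,
                                       method = c("pearson", "spearman")) {
  methylation_expression_correlation(score_a, score_b, match.arg(method))
}

#' Tumor vs normal AUROC by pair counting
#'
#' The probability that a randomly chosen tumor sample scores above a
#' randomly chosen normal sample, with half credit for ties -- computed
#' in closed form from mid-ranks, which is identical to exhaustive pair
#' counting. The p-value comes from the equivalent two-sided
#' Mann-Whitney U test.
#'
#' @param values numeric scores.
#' @param labels per-sample labels; `positive` marks the tumor class.
#' @param positive label of the positive (tumor) class.
#' @return list `auroc`, `p`, `n_pos`, `n_neg`.
#' @export
tumor_vs_normal_auroc <- function(values, labels, positive = "tumor") {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  rk <- rank(values)  # mid-ranks: ties get half credit
  auroc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  p <- suppressWarnings(
    wilcox.test(values[pos], values[!pos], exact = FALSE, correct = TRUE)
  )$p.value
  list(auroc = auroc, p = p, n_pos = n1, n_neg = n0)
}
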