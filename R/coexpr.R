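# Consensus seed-gene co-expression screen: per-cohort correlation,
# all-cohort consensus per histology, cross-histology intersection, and
# tumor-vs-normal differential-expression filtering.

#' Correlate every gene against a seed gene
#'
#' Computes, for each non-seed gene of a log2 expression matrix, the
#' Pearson (or Spearman) correlation with the seed gene, a two-sided
#' p-value from the t-transform of r, and Benjamini-Hochberg adjusted
#' q-values over all testable genes. Zero-variance genes are flagged
#' undefined and excluded from the adjustment.
#'
#' @param expr genes x samples numeric matrix with gene ids as rownames.
#' @param seed_gene id of the seed gene (must be a rowname).
#' @param method `"pearson"` or `"spearman"`.
#' @return data frame with columns `gene`, `r`, `p`, `q`, `n`, `flagged`.
#' @export
correlate_seed_gene <- function(expr, seed_gene,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!seed_gene %in% rownames(expr)) stop("seed gene absent: ", seed_gene)
  n <- ncol(expr)
  if (n < 3L) stop("need at least 3 samples")
  x <- expr[seed_gene, ]
  others <- expr[setdiff(rownames(expr), seed_gene), , drop = FALSE]
  if (method == "spearman") {
    x <- rank(x)
    others <- t(apply(others, 1L, rank))
  }
  sds <- apply(others, 1L, sd)
  flagged <- sds == 0 | sd(x) == 0
  r <- rep(NA_real_, nrow(others))
  r[!flagged] <- as.vector(cor(x, t(others[!flagged, , drop = FALSE])))
  p <- ifelse(flagged, NA_real_, r_to_p(r, n))
  q <- rep(NA_real_, length(p))
  q[!flagged] <- p.adjust(p[!flagged], method = "BH")
  data.frame(gene = rownames(others), r = r, p = p, q = q, n = n,
             flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus gene set across cohorts
#'
#' A gene enters the consensus iff its adjusted q-value is at or below
#' `alpha` in EVERY correlation table, and (optionally) the sign of r is
#' consistent across all cohorts.
#'
#' @param tables list of tables from [correlate_seed_gene()].
#' @param alpha per-cohort FDR threshold.
#' @param require_sign `"positive"`, `"negative"` or `"any"`.
#' @return list with `genes` (character, sorted) and `evidence` (one row
#'   per gene x cohort for the consensus genes).
#' @export
consensus_genes <- function(tables, alpha = 0.05,
                            require_sign = c("positive", "negative", "any")) {
  require_sign <- match.arg(require_sign)
  if (length(tables) == 0L) stop("empty table list")
  per_cohort <- lapply(tables, function(tb) {
    ok <- !tb$flagged & !is.na(tb$q) & tb$q <= alpha
    ok <- ok & switch(require_sign,
                      positive = tb$r > 0,
                      negative = tb$r < 0,
                      any = TRUE)
    tb$gene[ok]
  })
  genes <- sort(Reduce(intersect, per_cohort))
  if (require_sign == "any" && length(genes)) {
    # consistent sign still required when "any": same direction everywhere
    sign_tab <- vapply(tables, function(tb)
      sign(tb$r[match(genes, tb$gene)]), numeric(length(genes)))
    sign_tab <- matrix(sign_tab, nrow = length(genes))
    genes <- genes[apply(sign_tab, 1L, function(s) all(s == s[1]))]
  }
  evidence <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    sub <- tb[tb$gene %in% genes, c("gene", "r", "p", "q", "n")]
    if (nrow(sub)) sub$cohort <- names(tables)[i] %||% as.character(i)
    sub
  }))
  list(genes = genes, evidence = evidence)
}

#' Intersect two per-histology consensus sets
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return sorted character vector, the exact intersection.
#' @export
intersect_histologies <- function(set_a, set_b) sort(intersect(set_a, set_b))

#' Tumor-vs-normal differential-expression filter
#'
#' Two-sided Mann-Whitney U test per candidate gene (exact when both
#' groups have <= 8 samples and no ties, mid-rank normal approximation
#' with continuity correction otherwise), BH adjustment restricted to the
#' candidate set.
#'
#' @param expr genes x samples matrix.
#' @param groups per-sample labels containing `"tumor"` and `"normal"`.
#' @param genes candidate gene ids.
#' @param alpha FDR threshold on the candidate set.
#' @return list with `genes` (retained ids, sorted) and `stats` (per
#'   candidate: p, q, median difference and direction).
#' @export
differential_expression_filter <- function(expr, groups, genes, alpha = 0.05) {
  if (!all(genes %in% rownames(expr)))
    stop("genes absent from matrix: ",
         paste(setdiff(genes, rownames(expr)), collapse = ", "))
  tum <- groups == "tumor"; nrm <- groups == "normal"
  if (sum(tum) < 2L || sum(nrm) < 2L) stop("each group needs >= 2 samples")
  if (length(genes) == 0L)
    return(list(genes = character(0), stats = NULL))
  res <- lapply(genes, function(g) {
    xt <- expr[g, tum]; xn <- expr[g, nrm]
    p <- mw_test(xt, xn)$p
    d <- median(xt) - median(xn)
    data.frame(gene = g, p = p, median_diff = d,
               direction = if (d > 0) "up" else if (d < 0) "down" else "none",
               stringsAsFactors = FALSE)
  })
  stats <- do.call(rbind, res)
  stats$q <- p.adjust(stats$p, method = "BH")
  list(genes = sort(stats$gene[stats$q <= alpha]), stats = stats)
}

#' Run the full consensus co-expression signature cascade
#'
#' Executes, per cohort, the seed-gene correlation screen; forms the
#' all-cohort consensus within each histology; intersects the
#' histology-level sets; and filters the common signature by tumor vs
#' normal differential expression in a designated cohort. Mirrors the
#' multi-database screening cascade used to derive co-expression
#' signatures around a seed gene.
#'
#' @param collection a `cohort_collection`.
#' @param seed_gene seed gene id, present in every cohort.
#' @param alpha_corr per-cohort FDR threshold of the correlation screen.
#' @param alpha_de FDR threshold of the DE filter.
#' @param require_sign correlation sign constraint (see
#'   [consensus_genes()]).
#' @param method correlation method.
#' @param de_cohort name of the cohort used for the DE filter; default
#'   the first cohort containing both tumor and normal samples.
#' @return object of class `signature_result`: per-histology consensus
#'   sets, the common set, the DE-filtered set, per-stage counts, and the
#'   thresholds used.
#' @export
run_signature_pipeline <- function(collection, seed_gene,
                                   alpha_corr = 0.05, alpha_de = 0.05,
                                   require_sign = "positive",
                                   method = "pearson",
                                   de_cohort = NULL) {
  cohorts <- collection$cohorts
  if (length(cohorts) == 0L) stop("stage correlate: empty collection")
  histologies <- unique(vapply(cohorts, `[[`, "", "histology"))
  tables <- lapply(cohorts, function(co) {
    tryCatch(correlate_seed_gene(co$expr, seed_gene, method),
             error = function(e) stop("stage correlate [", co$name, "]: ",
                                      conditionMessage(e)))
  })
  per_hist <- lapply(histologies, function(h) {
    idx <- vapply(cohorts, function(co) co$histology == h, TRUE)
    consensus_genes(tables[idx], alpha = alpha_corr,
                    require_sign = require_sign)
  })
  names(per_hist) <- histologies
  common <- Reduce(intersect_histologies, lapply(per_hist, `[[`, "genes"))

  if (is.null(de_cohort)) {
    has_both <- vapply(cohorts, function(co)
      all(c("tumor", "normal") %in% co$groups), TRUE)
    if (!any(has_both)) stop("stage de_filter: no cohort with both groups")
    de_cohort <- names(cohorts)[which(has_both)[1]]
  }
  co <- cohorts[[de_cohort]]
  de <- if (length(common) == 0L) list(genes = character(0), stats = NULL)
        else tryCatch(
          differential_expression_filter(co$expr, co$groups, common, alpha_de),
          error = function(e) stop("stage de_filter: ", conditionMessage(e)))

  structure(list(
    seed_gene = seed_gene,
    per_histology = lapply(per_hist, `[[`, "genes"),
    common = common,
    de_filtered = de$genes,
    de_stats = de$stats,
    evidence = lapply(per_hist, `[[`, "evidence"),
    counts = c(vapply(per_hist, function(x) length(x$genes), 0L),
               common = length(common), de_filtered = length(de$genes)),
    thresholds = list(alpha_corr = alpha_corr, alpha_de = alpha_de,
                      require_sign = require_sign, method = method,
                      de_cohort = de_cohort)
  ), class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("Consensus co-expression signature (seed gene:", x$seed_gene, ")\n")
  for (h in names(x$per_histology))
    cat(sprintf("  %s consensus: %d genes\n", h, length(x$per_histology[[h]])))
  cat(sprintf("  common: %d genes\n  DE-filtered: %d genes\n",
              length(x$common), length(x$de_filtered)))
  invisible(x)
}
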