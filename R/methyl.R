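# Ordered-CpG promoter methylation analysis: group mean profiles, the
# cumulative per-CpG difference curve, per-CpG nonparametric testing,
# consistent-hypomethylation region calling, beta-threshold
# classification and sample clustering.

#' Validate and order a CpG promoter map
#'
#' A map is a BED-like data frame (`chrom`, `start`, `end`, `probe_id`,
#' `region_label`) of the promoter probes in position order. Positions
#' are 0-based half-open; region labels must form contiguous blocks in
#' the order north_shore, island, south_shore (a missing block is
#' allowed).
#'
#' @param df data frame with the five columns above.
#' @return the map, sorted by position, with class `cpg_map`.
#' @export
as_cpg_map <- function(df) {
  need <- c("chrom", "start", "end", "probe_id", "region_label")
  if (!all(need %in% names(df)))
    stop("map needs columns: ", paste(need, collapse = ", "))
  df <- df[order(df$chrom, df$start), need]
  rownames(df) <- NULL
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup)) stop("duplicated probe id: ", paste(unique(dup), collapse = ", "))
  for (ch in unique(df$chrom)) {
    pos <- df$start[df$chrom == ch]
    if (any(diff(pos) <= 0)) stop("non-monotone positions on ", ch)
  }
  known <- c("north_shore", "island", "south_shore")
  if (!all(df$region_label %in% known))
    stop("unknown region label: ",
         paste(setdiff(df$region_label, known), collapse = ", "))
  rl <- rle(df$region_label)$values
  if (anyDuplicated(rl) || is.unsorted(match(rl, known)))
    stop("region labels must form contiguous north_shore/island/south_shore blocks")
  class(df) <- c("cpg_map", "data.frame")
  df
}

#' Load a CpG map from a BED-like TSV file
#'
#' @param path tab-delimited file with header `chrom`, `start`, `end`,
#'   `probe_id`, `region_label`; rows may be in any order.
#' @return a `cpg_map` (see [as_cpg_map()]).
#' @export
load_cpg_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as_cpg_map(read_tsv(path, numeric_cols = c("start", "end")))
}

#' Per-group mean methylation profile in percent
#'
#' Means of beta x 100 per probe and group, with pairwise deletion of
#' missing values. Probes with under 50% coverage in either group are
#' excluded and recorded in the `"excluded"` attribute.
#'
#' @param beta probes x samples matrix of beta in `[0, 1]`.
#' @param groups per-sample `"tumor"`/`"normal"` labels.
#' @param map a `cpg_map` covering the probes.
#' @return data frame `probe_id`, `region_label`, `mean_pct_normal`,
#'   `mean_pct_tumor`, `n_normal`, `n_tumor`, in map order.
#' @export
group_mean_profile <- function(beta, groups, map) {
  if (!all(rownames(beta) %in% map$probe_id))
    stop("beta contains probes absent from the map")
  beta <- beta[map$probe_id[map$probe_id %in% rownames(beta)], , drop = FALSE]
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta outside [0, 1]")
  tum <- groups == "tumor"; nrm <- groups == "normal"
  if (!any(tum) || !any(nrm)) stop("both groups must be present")
  n_t <- rowSums(!is.na(beta[, tum, drop = FALSE]))
  n_n <- rowSums(!is.na(beta[, nrm, drop = FALSE]))
  prof <- data.frame(
    probe_id = rownames(beta),
    region_label = map$region_label[match(rownames(beta), map$probe_id)],
    mean_pct_normal = 100 * rowMeans(beta[, nrm, drop = FALSE], na.rm = TRUE),
    mean_pct_tumor = 100 * rowMeans(beta[, tum, drop = FALSE], na.rm = TRUE),
    n_normal = n_n, n_tumor = n_t,
    row.names = NULL, stringsAsFactors = FALSE
  )
  low <- n_t < sum(tum) / 2 | n_n < sum(nrm) / 2
  attr(prof, "excluded") <- prof$probe_id[low]
  prof[!low, , drop = FALSE]
}

#' Cumulative per-CpG methylation difference curve
#'
#' The per-probe difference `delta = normal - tumor` (percentage points)
#' and its running sum in map order. With this orientation, tumor
#' hypomethylation produces positive deltas and a rising cumulative
#' curve over affected shores, while regions with no group difference
#' (typically the unmethylated island) trace a flat segment.
#'
#' @param profile result of [group_mean_profile()].
#' @param map the `cpg_map` the profile was computed against.
#' @return data frame of class `cumdiff_profile` with `probe_id`,
#'   `region_label`, `delta`, `cumulative`.
#' @export
cumulative_difference <- function(profile, map) {
  expect <- map$probe_id[map$probe_id %in% profile$probe_id]
  if (!identical(profile$probe_id, expect))
    stop("profile probe order does not match the map")
  delta <- profile$mean_pct_normal - profile$mean_pct_tumor
  out <- data.frame(probe_id = profile$probe_id,
                    region_label = profile$region_label,
                    delta = delta, cumulative = cumsum(delta),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("cumdiff_profile", "data.frame")
  out
}

#' Per-CpG tumor vs normal Mann-Whitney tests
#'
#' Two-sided Mann-Whitney U per probe with BH adjustment across the
#' tested probes. Probes where either group has fewer than 2 non-missing
#' values are flagged untested (`NA` p and q).
#'
#' @inheritParams group_mean_profile
#' @return data frame `probe_id`, `p`, `q`, `tested`.
#' @export
per_cpg_test <- function(beta, groups) {
  tum <- groups == "tumor"; nrm <- groups == "normal"
  p <- apply(beta, 1L, function(row) {
    xt <- row[tum][!is.na(row[tum])]
    xn <- row[nrm][!is.na(row[nrm])]
    if (length(xt) < 2L || length(xn) < 2L) return(NA_real_)
    mw_test(xt, xn)$p
  })
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  data.frame(probe_id = rownames(beta), p = p, q = q, tested = !is.na(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call maximal runs of consistently hypomethylated CpGs
#'
#' A probe is "consistent" when `delta >= min_delta_pp` and
#' `q <= q_max`; calls are the maximal runs of consecutive consistent
#' probes of length at least `min_run`, reported in position order.
#' The defaults operationalize the steep rising segments of the
#' cumulative curve as runs of at least 5 CpGs each hypomethylated by at
#' least 5 percentage points at FDR 0.05.
#'
#' @param cumdiff a `cumdiff_profile`.
#' @param qvals result of [per_cpg_test()], aligned to the same map.
#' @param min_run minimum run length (default 5 consecutive CpGs).
#' @param min_delta_pp minimum per-CpG hypomethylation, percentage points.
#' @param q_max per-CpG FDR ceiling.
#' @return data frame, one row per call: `start`, `end` (probe indices),
#'   `probe_start`, `probe_end`, `run_length`, `mean_delta`,
#'   `regions_spanned`.
#' @export
detect_consistent_region <- function(cumdiff, qvals, min_run = 5,
                                     min_delta_pp = 5, q_max = 0.05) {
  if (min_run < 1) stop("min_run must be >= 1")
  q <- qvals$q[match(cumdiff$probe_id, qvals$probe_id)]
  ok <- !is.na(q) & q <= q_max & cumdiff$delta >= min_delta_pp
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  calls <- lapply(which(keep), function(i) {
    s <- starts[i]; e <- ends[i]
    data.frame(start = s, end = e,
               probe_start = cumdiff$probe_id[s],
               probe_end = cumdiff$probe_id[e],
               run_length = e - s + 1L,
               mean_delta = mean(cumdiff$delta[s:e]),
               regions_spanned = paste(unique(cumdiff$region_label[s:e]),
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  if (length(calls) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      probe_start = character(0), probe_end = character(0),
                      run_length = integer(0), mean_delta = numeric(0),
                      regions_spanned = character(0)))
  do.call(rbind, calls)
}

#' Classify beta values as methylated or unmethylated
#'
#' The conventional Infinium classification: a sample is methylated when
#' beta is at or above the threshold (default 0.5; the boundary value
#' falls in the methylated class).
#'
#' @param beta numeric vector in `[0, 1]`.
#' @param threshold classification cut, default 0.5.
#' @return character vector `"methylated"`/`"unmethylated"`.
#' @export
classify_methylation <- function(beta, threshold = 0.5) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta outside [0, 1]")
  ifelse(beta >= threshold, "methylated", "unmethylated")
}

#' Hierarchically cluster samples on their methylation profiles
#'
#' Agglomerative clustering with Euclidean distance between sample beta
#' vectors and average linkage. Leaf order is the deterministic
#' `stats::hclust` order (ties broken by input column order).
#'
#' @param beta probes x samples matrix.
#' @return list with `hclust` (the fit), `order` (leaf order) and
#'   `labels`.
#' @export
cluster_samples <- function(beta) {
  if (ncol(beta) < 2L) stop("need at least 2 samples")
  all_missing <- colSums(!is.na(beta)) == 0
  if (any(all_missing))
    stop("all-missing sample: ",
         paste(colnames(beta)[all_missing], collapse = ", "))
  hc <- hclust(dist(t(beta), method = "euclidean"), method = "average")
  list(hclust = hc, order = hc$order, labels = hc$labels)
}
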