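map_df <- function() {
  data.frame(chrom = "chr6",
             start = c(100L, 200L, 300L, 400L, 500L),
             end = c(101L, 201L, 301L, 401L, 501L),
             probe_id = sprintf("cg%08d", 1:5),
             region_label = c("north_shore", "north_shore", "island",
                              "island", "south_shore"),
             stringsAsFactors = FALSE)
}

test_that("CpG map loading validates, sorts and rejects malformed input", {
  df <- map_df()
  path <- tempfile(fileext = ".tsv")
  write.table(df[c(3, 1, 5, 2, 4), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  map <- load_cpg_map(path)
  expect_s3_class(map, "cpg_map")
  expect_identical(map$probe_id, df$probe_id)  # order normalized

  dup <- df; dup$probe_id[2] <- "cg00000001"; dup$start[2] <- 150L
  expect_error(as_cpg_map(dup), "cg00000001")
  bad <- df; bad$start[2] <- 100L
  expect_error(as_cpg_map(bad), "non-monotone")
  lab <- df; lab$region_label[1] <- "open_sea"
  expect_error(as_cpg_map(lab), "unknown region label")
  split_island <- df
  split_island$region_label <- c("island", "north_shore", "island",
                                 "island", "south_shore")
  expect_error(as_cpg_map(split_island), "contiguous")
  expect_error(load_cpg_map(tempfile()), "no such file")
})

test_that("group mean profiles do simple arithmetic and ignore column
           order", {
  map <- as_cpg_map(map_df())
  beta <- matrix(c(0.2, 0.4, 0.6, 0.8), nrow = 2,
                 dimnames = list(map$probe_id[1:2], c("t1", "n1")))
  groups <- c("tumor", "normal")
  prof <- group_mean_profile(beta, groups, map)
  expect_equal(prof$mean_pct_tumor, c(20, 40))
  expect_equal(prof$mean_pct_normal, c(60, 80))

  beta5 <- matrix(0.5, nrow = 5, ncol = 4,
                  dimnames = list(map$probe_id, sprintf("s%d", 1:4)))
  g4 <- c("tumor", "tumor", "normal", "normal")
  prof5 <- group_mean_profile(beta5, g4, map)
  expect_true(all(prof5$mean_pct_normal == 50 & prof5$mean_pct_tumor == 50))

  set.seed(1)
  betar <- matrix(runif(20), nrow = 5,
                  dimnames = list(map$probe_id, sprintf("s%d", 1:4)))
  perm <- c(3, 1, 4, 2)
  expect_equal(group_mean_profile(betar, g4, map),
               group_mean_profile(betar[, perm], g4[perm], map))
})

test_that("cumulative difference is the prefix sum of normal - tumor", {
  map <- as_cpg_map(map_df())
  prof <- data.frame(probe_id = map$probe_id,
                     region_label = map$region_label,
                     mean_pct_normal = c(60, 55, 10, 10, 58),
                     mean_pct_tumor = c(40, 35, 10, 10, 48),
                     n_normal = 10, n_tumor = 10,
                     stringsAsFactors = FALSE)
  cd <- cumulative_difference(prof, map)
  expect_equal(cd$delta, c(20, 20, 0, 0, 10))
  expect_equal(cd$cumulative, c(20, 40, 40, 40, 50))
  # invariants: step identity and conservation of the total
  expect_equal(diff(cd$cumulative), cd$delta[-1])
  expect_equal(cd$cumulative[nrow(cd)], sum(cd$delta))
  # identical group profiles trace a flat curve
  prof0 <- prof; prof0$mean_pct_tumor <- prof0$mean_pct_normal
  cd0 <- cumulative_difference(prof0, map)
  expect_true(all(cd0$delta == 0) && all(cd0$cumulative == 0))
  # misaligned order is refused
  expect_error(cumulative_difference(prof[c(2, 1, 3, 4, 5), ], map),
               "order")
})

test_that("per-CpG test: exact small-sample p, p = 1 on identical
           groups, degenerate probes flagged", {
  beta <- rbind(cg1 = c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8),
                cg2 = c(0.4, 0.5, 0.6, 0.4, 0.5, 0.6),
                cg3 = c(0.2, NA, NA, 0.3, 0.4, 0.5))
  groups <- rep(c("tumor", "normal"), each = 3)
  res <- per_cpg_test(beta, groups)
  expect_equal(res$p[1], 0.1, tolerance = 1e-12)
  expect_equal(res$p[1], brute_mw_exact_p(beta[1, 1:3], beta[1, 4:6]),
               tolerance = 1e-12)
  expect_equal(res$p[2], 1)
  expect_false(res$tested[3])
  expect_true(is.na(res$q[3]))
})

test_that("region calling finds maximal runs and splits on a failing
           probe", {
  n <- 20
  map <- as_cpg_map(data.frame(
    chrom = "chr6", start = 1:n * 100L, end = 1:n * 100L + 1L,
    probe_id = sprintf("cg%08d", 1:n),
    region_label = rep(c("north_shore", "island", "south_shore"),
                       c(14, 3, 3)), stringsAsFactors = FALSE))
  delta <- rep(0, n)
  delta[3:13] <- 20
  delta[8] <- 1          # failing probe splits the run
  cd <- data.frame(probe_id = map$probe_id, region_label = map$region_label,
                   delta = delta, cumulative = cumsum(delta),
                   stringsAsFactors = FALSE)
  q <- ifelse(delta >= 20, 0.001, 0.9)
  qv <- data.frame(probe_id = map$probe_id, p = q, q = q, tested = TRUE)
  calls <- detect_consistent_region(cd, qv, min_run = 5)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$start, c(3L, 9L))
  expect_equal(calls$end, c(7L, 13L))
  expect_equal(calls$run_length, c(5L, 5L))
  # null input: no calls
  qv0 <- qv; qv0$q <- 0.9
  expect_equal(nrow(detect_consistent_region(cd, qv0)), 0L)
  expect_error(detect_consistent_region(cd, qv, min_run = 0), "min_run")
})

test_that("region calls ignore probes outside the promoter span", {
  # appending flat probes after the south shore leaves the call unchanged
  base <- 12
  mk <- function(n_extra) {
    n <- base + n_extra
    map <- as_cpg_map(data.frame(
      chrom = "chr6", start = 1:n * 10L, end = 1:n * 10L + 1L,
      probe_id = sprintf("cg%08d", 1:n),
      region_label = rep(c("north_shore", "island", "south_shore"),
                         c(8, 2, n - 10)), stringsAsFactors = FALSE))
    delta <- rep(0, n); delta[2:6] <- 15
    cd <- data.frame(probe_id = map$probe_id,
                     region_label = map$region_label, delta = delta,
                     cumulative = cumsum(delta), stringsAsFactors = FALSE)
    q <- ifelse(delta > 0, 1e-4, 0.8)
    detect_consistent_region(
      cd, data.frame(probe_id = map$probe_id, p = q, q = q, tested = TRUE))
  }
  expect_equal(mk(2)[, c("start", "end")], mk(10)[, c("start", "end")])
})

test_that("beta classification applies the 0.5 threshold with the
           boundary in the methylated class", {
  expect_equal(classify_methylation(0.6), "methylated")
  expect_equal(classify_methylation(0.2), "unmethylated")
  expect_equal(classify_methylation(0.5), "methylated")
  expect_equal(classify_methylation(c(0.3, 0.7), threshold = 0.4),
               c("unmethylated", "methylated"))
  expect_error(classify_methylation(1.2), "outside")
})

test_that("sample clustering merges identical samples at height zero and
           recovers planted clusters", {
  set.seed(5)
  b <- matrix(runif(30), nrow = 10)
  beta <- cbind(b[, 1], b[, 1], b[, 2:3])
  colnames(beta) <- sprintf("s%d", 1:4)
  cl <- cluster_samples(beta)
  expect_equal(min(cl$hclust$height), 0)
  first_merge <- cl$hclust$merge[1, ]
  expect_setequal(-first_merge, c(1L, 2L))

  # two well-separated groups: the 2-cut matches the planted split
  g1 <- matrix(rnorm(10 * 6, 0, 0.05), 10)
  g2 <- matrix(rnorm(10 * 6, 1, 0.05), 10)
  beta2 <- pmin(pmax(cbind(g1, g2), 0), 1)
  colnames(beta2) <- sprintf("s%d", 1:12)
  k2 <- stats::cutree(cluster_samples(beta2)$hclust, k = 2)
  expect_equal(length(unique(k2[1:6])), 1L)
  expect_equal(length(unique(k2[7:12])), 1L)
  expect_false(k2[1] == k2[7])

  bad <- beta; bad[, 2] <- NA
  expect_error(cluster_samples(bad), "all-missing")
})
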