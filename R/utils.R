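# Internal helpers shared across modules.

# Derive a child RNG seed from the global seed. Offsets are fixed per
# generator so that one integer reproduces the whole simulation; result is
# kept inside the 32-bit integer range R requires of set.seed().
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 10007) %% 2147483647L)
}

# Two-sided Mann-Whitney U test used for both the DE filter and the
# per-CpG comparisons: exact enumeration when both groups have <= 8
# observations and no ties, mid-rank normal approximation with continuity
# correction otherwise.
mw_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

# Pearson/Spearman coefficient with a two-sided p from the t-transform
# t = r * sqrt((n - 2) / (1 - r^2)). Spearman applies the same transform
# to the rank correlation (large-sample approximation).
cor_with_p <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- cor(x, y)
  p <- r_to_p(r, n)
  list(r = r, p = p, n = n, method = method)
}

r_to_p <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), df = n - 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("'%s' must be a single integer >= 1", name))
  invisible(x)
}
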