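# Independent brute-force oracles, kept deliberately naive so they share
# no code path with the implementation they check.

# Pearson r from the raw definitional sums
brute_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- sum(x * y) - sx * sy / n
  den <- sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
  num / den
}

# Exact two-sided Mann-Whitney p by full enumeration of all label
# assignments of the pooled sample (feasible for small groups)
brute_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  centre <- m * length(y) / 2
  idx <- utils::combn(length(pooled), m)
  u_all <- apply(idx, 2L, function(i) u_stat(pooled[i], pooled[-i]))
  mean(abs(u_all - centre) >= abs(u_obs - centre) - 1e-12)
}

# AUROC by exhaustive pair counting with half credit for ties
brute_auroc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Small covariate table for survival generators
make_surv_covariates <- function(n, seed = 1, marker = NULL) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             marker = if (is.null(marker)) rnorm(n) else marker,
             age = round(rnorm(n, 65, 8)),
             sex = rbinom(n, 1, 0.5),
             smoking = rbinom(n, 1, 0.6),
             stringsAsFactors = FALSE)
}

# Compact simulation settings reused across tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_cohorts_per_histology = 1, n_samples_tumor = 20,
         n_samples_normal = 20, n_genes = 300, module_size = 10),
    list(...))
  do.call(simulation_config, args)
}
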