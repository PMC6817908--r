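test_that("dichotomization rules cut where they should and send the
           boundary up", {
  labs <- dichotomize(c(1, 2, 3, 4), "median")
  expect_equal(unclass(labs)[1:4], c("low", "low", "high", "high"),
               ignore_attr = TRUE)
  expect_equal(attr(labs, "cut"), 2.5)
  expect_equal(as.character(dichotomize(c(0.6, 0.2), "beta_threshold")),
               c("methylated", "unmethylated"))
  # boundary value lands in the upper class
  expect_equal(as.character(dichotomize(c(0.5, 0.4), "beta_threshold")),
               c("methylated", "unmethylated"))
  # mean and median disagree on a skewed toy
  skew <- c(1, 1, 1, 9)
  expect_equal(attr(dichotomize(skew, "mean"), "cut"), 3)
  expect_equal(attr(dichotomize(skew, "median"), "cut"), 1)
  expect_false(identical(as.character(dichotomize(skew, "mean")),
                         as.character(dichotomize(skew, "median"))))
  expect_error(dichotomize(rep(2, 5), "median"), "degenerate")
})

test_that("Kaplan-Meier equals the hand product-limit", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 2 / 3)  # censoring leaves S flat
  expect_equal(km$surv[km$time == 3], 0)
  # all censored: S identically 1
  km0 <- kaplan_meier(c(2, 5, 7), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # duplicating every subject leaves the curve unchanged
  t1 <- c(1, 3, 4, 6); e1 <- c(1, 0, 1, 1)
  a <- kaplan_meier(t1, e1)
  b <- kaplan_meier(rep(t1, 2), rep(e1, 2))
  expect_equal(a$surv[a$n_event > 0], b$surv[b$n_event > 0])
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank matches the hand hypergeometric tabulation", {
  # A = {1, 3} both events, B = {2, 4} both events: chi-square = 8/13
  lr <- logrank_test(c(1, 3, 2, 4), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr$statistic, 8 / 13, tolerance = 1e-8)
  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(c(1, 2, 1, 2), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-10)
  expect_error(logrank_test(1:3, rep(1, 3), rep("A", 3)), "two groups")
})

test_that("Cox fit recovers a planted hazard ratio and refuses
           uninformative markers", {
  cfg <- simulation_config(rng_seed = 19)
  covs <- make_surv_covariates(300, seed = 19)
  sv <- generate_survival(covs, cfg)
  fit <- cox_fit(sv, "marker")
  hr <- fit$coefficients$hr[fit$coefficients$term == "marker"]
  expect_gt(hr, 1.5)
  expect_lt(hr, 2.7)
  expect_true(fit$converged)
  # HR = exp(coef) and the CI brackets it
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
  expect_true(all(fit$coefficients$ci_lo <= fit$coefficients$hr &
                    fit$coefficients$hr <= fit$coefficients$ci_hi))
  sv$flat <- 1
  expect_error(cox_fit(sv, "flat"), "constant covariate")
  expect_error(cox_fit(sv[1:3, ], "marker"), "fewer events")
})

test_that("predicted survival curves decrease with a hazardous marker", {
  cfg <- simulation_config(rng_seed = 23)
  sv <- generate_survival(make_surv_covariates(200, seed = 23), cfg)
  fit <- cox_fit(sv, "marker")
  ps <- cox_predicted_survival(fit, marker_values = c(-1, 1))
  s_lo <- ps[ps$marker_value == -1, ]
  s_hi <- ps[ps$marker_value == 1, ]
  expect_true(all(s_hi$surv <= s_lo$surv + 1e-12))
})

test_that("nested LRT is exactly zero on identical fits and rejects
           non-nested or mismatched models", {
  cfg <- simulation_config(rng_seed = 29)
  sv <- generate_survival(make_surv_covariates(150, seed = 29), cfg)
  sv$noise <- rnorm(150)
  full <- cox_fit(sv, "marker", confounders = c("age", "noise"))
  red <- cox_fit(sv, "marker", confounders = "age")
  self <- nested_lrt(full, full)
  expect_identical(self$statistic, 0)
  expect_identical(self$p, 1)
  lrt <- nested_lrt(full, red)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1L)
  other <- cox_fit(sv, "noise", confounders = "sex")
  expect_error(nested_lrt(full, other), "not nested")
  red_sub <- cox_fit(sv[1:120, ], "marker", confounders = "age")
  expect_error(nested_lrt(full, red_sub), "mismatched sample sets")
})

test_that("elastic-net selection shrinks to empty under a huge penalty
           and finds a planted prognostic CpG", {
  cfg <- simulation_config(rng_seed = 37, hazard_log_hr = log(3))
  set.seed(37)
  n <- 300
  cpgs <- matrix(runif(n * 20, 0.2, 0.8), n,
                 dimnames = list(NULL, sprintf("cg%03d", 1:20)))
  covs <- make_surv_covariates(n, seed = 37,
                               marker = as.numeric(scale(cpgs[, 7])))
  sv <- generate_survival(covs, cfg)
  # huge fixed penalty: full shrinkage
  empty <- elastic_net_cox_select(cpgs, sv, lambda = 1e6)
  expect_length(empty$selected, 0)
  expect_null(empty$refit)
  # cross-validated penalty: the prognostic CpG is selected
  sel <- elastic_net_cox_select(cpgs, sv, seed = 37)
  expect_true("cg007" %in% sel$selected)
  expect_s3_class(sel$refit, "cox_fit")
  # reproducible under the same seed
  sel2 <- elastic_net_cox_select(cpgs, sv, seed = 37)
  expect_identical(sel$selected, sel2$selected)
  expect_error(elastic_net_cox_select(matrix(1, n, 2), sv), "zero variance")
})

test_that("bootstrap validation runs at B = 1 and corrects optimism on a
           prognostic marker", {
  cfg <- simulation_config(rng_seed = 41, hazard_log_hr = log(3))
  sv <- generate_survival(make_surv_covariates(200, seed = 41), cfg)
  fml <- survival::Surv(dfs_time, dfs_event) ~ marker
  one <- bootstrap_validate(sv, fml, B = 1, seed = 1)
  expect_true(is.finite(one$corrected))
  expect_error(bootstrap_validate(sv, fml, B = 0), "B must be")
  val <- bootstrap_validate(sv, fml, B = 50, seed = 2)
  expect_gt(val$corrected, 0.65)  # strongly prognostic marker
  expect_true(is.finite(val$optimism))
})
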