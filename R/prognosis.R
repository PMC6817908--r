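# Prognostic layer: dichotomization, Kaplan-Meier, log-rank,
# confounder-adjusted Cox models, elastic-net CpG selection, bootstrap
# internal validation, and the nested likelihood-ratio test.

#' Dichotomize a marker into two prognostic groups
#'
#' @param values numeric marker (expression or beta).
#' @param rule `"median"`, `"mean"`, or `"beta_threshold"` (fixed cut at
#'   `threshold`). The boundary value is assigned to the upper class.
#' @param threshold cut used by `beta_threshold`, default 0.5.
#' @return character labels (`"high"`/`"low"`, or
#'   `"methylated"`/`"unmethylated"` for `beta_threshold`), with the cut
#'   value in the `"cut"` attribute.
#' @export
dichotomize <- function(values, rule = c("median", "mean", "beta_threshold"),
                        threshold = 0.5) {
  rule <- match.arg(rule)
  if (length(values) < 2L) stop("need at least 2 samples")
  if (rule != "beta_threshold" && length(unique(values)) == 1L)
    stop("degenerate split: all values identical")
  cut <- switch(rule, median = median(values), mean = mean(values),
                beta_threshold = threshold)
  labels <- if (rule == "beta_threshold")
    classify_methylation(values, cut)
  else ifelse(values >= cut, "high", "low")
  attr(labels, "rule") <- rule
  attr(labels, "cut") <- cut
  labels
}

#' Kaplan-Meier product-limit curves
#'
#' @param times follow-up times (months); must be non-negative.
#' @param events 1 = event, 0 = censored.
#' @param groups optional per-sample group labels (one curve per group).
#' @return data frame with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`; the `survfit` object is kept in the `"fit"`
#'   attribute.
#' @export
kaplan_meier <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("negative times")
  df <- data.frame(times = times, events = events,
                   groups = if (is.null(groups)) "all" else groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = df)
  strata <- if (is.null(fit$strata)) rep("all", length(fit$time))
            else rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  out <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Log-rank test between survival groups
#'
#' @inheritParams kaplan_meier
#' @param groups per-sample group labels; at least two non-empty groups.
#' @return list `statistic` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  if (length(unique(groups)) < 2L) stop("need at least two groups")
  df <- data.frame(times = times, events = events, groups = groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups, data = df)
  k <- length(unique(groups)) - 1L
  list(statistic = unname(sd$chisq), df = k,
       p = pchisq(sd$chisq, df = k, lower.tail = FALSE))
}

surv_endpoint <- function(table, endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  survival::Surv(table[[paste0(endpoint, "_time")]],
                 table[[paste0(endpoint, "_event")]])
}

#' Confounder-adjusted Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron tie handling) of a marker plus
#' confounders on DFS or OS. The log partial likelihood is retained for
#' nested likelihood-ratio testing; predicted survival over the marker's
#' observed range (at mean confounder levels) is available through
#' [cox_predicted_survival()].
#'
#' @param table a `survival_table` (or data frame with `<endpoint>_time`
#'   / `<endpoint>_event` columns).
#' @param marker name of the marker column.
#' @param confounders confounder column names; defaults to age, sex,
#'   smoking.
#' @param endpoint `"dfs"` or `"os"`.
#' @return object of class `cox_fit`: `coefficients` (term, coef, se,
#'   hr, ci, p), `loglik`, `loglik_null`, `n`, `events`, `converged`,
#'   and the underlying `coxph` model.
#' @export
cox_fit <- function(table, marker, confounders = c("age", "sex", "smoking"),
                    endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  covs <- c(marker, confounders)
  missing_cols <- setdiff(covs, names(table))
  if (length(missing_cols))
    stop("columns absent from table: ", paste(missing_cols, collapse = ", "))
  y <- surv_endpoint(table, endpoint)
  n_par <- length(covs)
  if (sum(y[, "status"]) < n_par)
    stop("fewer events than parameters")
  for (cv in covs)
    if (is.numeric(table[[cv]]) && var(table[[cv]]) == 0)
      stop("constant covariate (no information): ", cv)
  fml <- stats::as.formula(paste("y ~", paste(covs, collapse = " + ")))
  dat <- cbind(data.frame(y = y), table[covs])
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  ci <- summary(fit)$conf.int
  if (any(abs(co[, "coef"]) > 15))
    stop("complete separation: diverging coefficient")
  out <- structure(list(
    coefficients = data.frame(
      term = rownames(co), coef = co[, "coef"], se = co[, "se(coef)"],
      hr = exp(co[, "coef"]), ci_lo = ci[, "lower .95"],
      ci_hi = ci[, "upper .95"], p = co[, "Pr(>|z|)"],
      row.names = NULL, stringsAsFactors = FALSE),
    loglik = fit$loglik[2], loglik_null = fit$loglik[1],
    n = fit$n, events = fit$nevent, converged = converged,
    marker = marker, confounders = confounders, endpoint = endpoint,
    model = fit, data = dat
  ), class = "cox_fit")
  out
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s, %d samples, %d events%s)\n", toupper(x$endpoint),
              x$n, x$events, if (x$converged) "" else ", NOT converged"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Model-predicted survival over the observed marker range
#'
#' Renders a continuous-marker Cox model as predicted survival curves at
#' chosen marker values, holding confounders at their means.
#'
#' @param fit a [cox_fit()].
#' @param marker_values marker values to predict at; default the
#'   quartiles of the observed range.
#' @return data frame `marker_value`, `time`, `surv`.
#' @export
cox_predicted_survival <- function(fit, marker_values = NULL) {
  stopifnot(inherits(fit, "cox_fit"))
  obs <- fit$data[[fit$marker]]
  if (is.null(marker_values))
    marker_values <- unname(quantile(obs, c(0.25, 0.5, 0.75)))
  newdata <- fit$data[rep(1L, length(marker_values)),
                      c(fit$marker, fit$confounders), drop = FALSE]
  newdata[[fit$marker]] <- marker_values
  for (cv in fit$confounders)
    if (is.numeric(newdata[[cv]])) newdata[[cv]] <- mean(fit$data[[cv]])
  sf <- survival::survfit(fit$model, newdata = newdata)
  surv <- as.matrix(sf$surv)
  do.call(rbind, lapply(seq_along(marker_values), function(i)
    data.frame(marker_value = marker_values[i], time = sf$time,
               surv = surv[, i])))
}

#' Elastic-net penalized Cox selection of prognostic CpGs
#'
#' Fits the penalized Cox path over candidate CpG betas, chooses the
#' penalty by cross-validated partial likelihood (`"lambda.1se"` by
#' default), and refits the selected CpGs unpenalized together with the
#' confounders. Fully seeded through the fold assignment.
#'
#' @param beta_candidates samples x CpGs numeric matrix (rows aligned to
#'   `table`).
#' @param table a `survival_table` including the confounder columns.
#' @param mixing elastic-net mixing parameter alpha in `[0, 1]`
#'   (1 = lasso); default 0.5.
#' @param cv_folds cross-validation folds; requires at least as many
#'   events.
#' @param seed integer seed for the fold assignment.
#' @param lambda `"lambda.1se"`, `"lambda.min"`, or a fixed numeric
#'   penalty (skips cross-validation; `Inf`-like values give the empty
#'   selection).
#' @param confounders confounders for the unpenalized refit.
#' @param endpoint `"dfs"` or `"os"`.
#' @return list of class `selection_result`: `selected`, `lambda`,
#'   `mixing`, `cv_folds`, `seed`, `path` (per-lambda df summary), and
#'   `refit` (a [cox_fit()] on the selected CpGs, `NULL` when none).
#' @export
elastic_net_cox_select <- function(beta_candidates, table, mixing = 0.5,
                                   cv_folds = 10, seed = 1,
                                   lambda = "lambda.1se",
                                   confounders = c("age", "sex", "smoking"),
                                   endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  x <- as.matrix(beta_candidates)
  if (ncol(x) < 1L) stop("need at least one candidate CpG")
  if (all(apply(x, 2L, var) == 0)) stop("all candidates have zero variance")
  y <- surv_endpoint(table, endpoint)
  n_events <- sum(y[, "status"])
  chosen <- NA_real_
  if (is.numeric(lambda)) {
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = mixing)
    chosen <- lambda
    cf <- as.matrix(glmnet::coef.glmnet(fit, s = chosen, exact = FALSE))
  } else {
    if (n_events < cv_folds)
      stop("fewer events (", n_events, ") than cv_folds")
    set.seed(as.integer(seed))
    foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(x)))
    cvfit <- glmnet::cv.glmnet(x, y, family = "cox", alpha = mixing,
                               foldid = foldid)
    chosen <- cvfit[[lambda]]
    cf <- as.matrix(glmnet::coef.glmnet(cvfit, s = lambda))
  }
  selected <- rownames(cf)[cf[, 1] != 0]
  refit <- NULL
  if (length(selected)) {
    tab2 <- cbind(table, as.data.frame(x[, selected, drop = FALSE]))
    refit <- cox_fit(tab2, marker = selected[1],
                     confounders = c(selected[-1], confounders),
                     endpoint = endpoint)
  }
  structure(list(selected = selected, lambda = chosen, mixing = mixing,
                 cv_folds = if (is.numeric(lambda)) NA_integer_ else cv_folds,
                 seed = seed, n_events = n_events,
                 refit = refit), class = "selection_result")
}

#' Bootstrap optimism-corrected concordance index
#'
#' Harrell internal validation: the apparent c-index of a Cox model
#' minus the mean optimism across `B` bootstrap resamples (bootstrap
#'-train c minus bootstrap-model-on-original-data c).
#'
#' @param table data frame with the survival and covariate columns.
#' @param formula a Cox model formula, e.g.
#'   `Surv(dfs_time, dfs_event) ~ marker + age`.
#' @param B bootstrap replicates (>= 1); 1000 for a production run.
#' @param seed integer seed.
#' @return list `apparent`, `optimism`, `corrected`, `B`, `n_failed`.
#' @export
bootstrap_validate <- function(table, formula, B = 1000, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  fit0 <- survival::coxph(formula, data = table, ties = "efron")
  apparent <- survival::concordance(fit0)$concordance
  y <- stats::model.response(stats::model.frame(formula, table))
  set.seed(as.integer(seed))
  opt <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample(nrow(table), replace = TRUE)
    # warnings on resamples (flat likelihoods, tied risk sets) are routine
    fit_b <- tryCatch(
      suppressWarnings(
        survival::coxph(formula, data = table[idx, , drop = FALSE],
                        ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit_b)) next
    c_train <- survival::concordance(fit_b)$concordance
    lp <- stats::predict(fit_b, newdata = table, type = "lp")
    c_test <- survival::concordance(y ~ lp, reverse = TRUE)$concordance
    opt[b] <- c_train - c_test
  }
  n_failed <- sum(is.na(opt))
  optimism <- mean(opt, na.rm = TRUE)
  list(apparent = apparent, optimism = optimism,
       corrected = apparent - optimism, B = B, n_failed = n_failed)
}

#' Nested likelihood-ratio test between two Cox fits
#'
#' Twice the difference in log partial likelihood, chi-square on the
#' difference in parameter count. Used to ask whether adding a second
#' marker improves a one-marker prognostic model.
#'
#' @param fit_full,fit_reduced [cox_fit()] objects on the same samples;
#'   the reduced model's covariates must be a subset of the full
#'   model's.
#' @return list `statistic`, `df`, `p`.
#' @export
nested_lrt <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "cox_fit"), inherits(fit_reduced, "cox_fit"))
  terms_full <- fit_full$coefficients$term
  terms_red <- fit_reduced$coefficients$term
  if (!all(terms_red %in% terms_full))
    stop("models are not nested")
  if (fit_full$n != fit_reduced$n || fit_full$events != fit_reduced$events)
    stop("mismatched sample sets")
  stat <- 2 * (fit_full$loglik - fit_reduced$loglik)
  if (stat < -1e-8) stop("models are not nested: negative statistic")
  stat <- max(stat, 0)
  df <- length(terms_full) - length(terms_red)
  p <- if (df == 0L) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p)
}
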