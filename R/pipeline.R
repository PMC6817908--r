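# End-to-end orchestration: one config drives simulation (or bundle
# loading), the co-expression screen, the methylation analysis, the
# integration statistics and the prognostic models, with every default
# recorded in a machine-readable summary.

#' Build a validated pipeline run configuration
#'
#' Exactly one of `sim` (a [simulation_config()], synthetic inputs) or
#' `input_dir` (a fixture bundle on disk) must be supplied.
#'
#' @param sim a [simulation_config()] or `NULL`.
#' @param input_dir directory written by [write_fixture_bundle()] or
#'   `NULL`.
#' @param out_dir output directory for per-stage TSVs and the JSON
#'   summary (`NULL` = no files written).
#' @param alpha_corr,alpha_de,require_sign co-expression thresholds.
#' @param min_run,min_delta_pp,q_max region-calling thresholds.
#' @param beta_threshold methylation classification cut.
#' @param enet_mixing,enet_folds elastic-net settings.
#' @param bootstrap_B bootstrap replicates for internal validation.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(sim = NULL, input_dir = NULL, out_dir = NULL,
                       alpha_corr = 0.05, alpha_de = 0.05,
                       require_sign = "positive",
                       min_run = 5, min_delta_pp = 5, q_max = 0.05,
                       beta_threshold = 0.5,
                       enet_mixing = 0.5, enet_folds = 10,
                       bootstrap_B = 200) {
  if (is.null(sim) == is.null(input_dir))
    stop("exactly one of 'sim' or 'input_dir' must be given")
  if (!is.null(sim)) stopifnot(inherits(sim, "simulation_config"))
  stopifnot(alpha_corr > 0, alpha_corr < 1, alpha_de > 0, alpha_de < 1,
            min_run >= 1, q_max > 0, q_max <= 1,
            beta_threshold >= 0, beta_threshold <= 1,
            enet_mixing >= 0, enet_mixing <= 1, bootstrap_B >= 1)
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 alpha_corr = alpha_corr, alpha_de = alpha_de,
                 require_sign = require_sign, min_run = min_run,
                 min_delta_pp = min_delta_pp, q_max = q_max,
                 beta_threshold = beta_threshold,
                 enet_mixing = enet_mixing, enet_folds = enet_folds,
                 bootstrap_B = bootstrap_B),
            class = "run_config")
}

#' Run the full discovery pipeline from a single configuration
#'
#' Stages: simulate (or load) the linked cohorts, run the consensus
#' co-expression cascade, the promoter methylation analysis (profiles,
#' cumulative-difference curve, per-CpG tests, region calls), the
#' integration statistics (coupling, cross-promoter correlation, AUROC
#' of the promoter score) and the prognostic models (Cox with
#' confounders, elastic-net selection, bootstrap validation, nested
#' LRT). When `out_dir` is set, per-stage TSVs and a JSON summary are
#' written; the summary embeds every threshold used.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with per-stage results and a
#'   `summary` list (the JSON content).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$sim)) {
    expression <- generate_expression_cohorts(config$sim)
    methylation <- generate_methylation(config$sim)
    truth <- expression$truth
    collection <- expression$collection
    seed_gene <- truth$seed_gene
    region_probes <- methylation$map$probe_id[
      truth$planted_region_bounds["start"]:truth$planted_region_bounds["end"]]
    score_all <- promoter_score(methylation$beta, region_probes,
                                methylation$map)
    tum <- methylation$groups == "tumor"
    set.seed(child_seed(config$sim$rng_seed, 4L))
    covs <- data.frame(sample_id = colnames(methylation$beta)[tum],
                       marker = as.numeric(scale(score_all[tum])),
                       age = round(rnorm(sum(tum), 65, 8)),
                       sex = rbinom(sum(tum), 1, 0.5),
                       smoking = rbinom(sum(tum), 1, 0.6))
    surv_tab <- generate_survival(covs, config$sim)
  } else {
    bundle <- read_fixture_bundle(config$input_dir)
    collection <- bundle$expression$collection
    methylation <- bundle$methylation
    truth <- bundle$truth
    surv_tab <- bundle$survival
    seed_gene <- truth$seed_gene
    region_probes <- methylation$map$probe_id[
      truth$planted_region_bounds["start"]:truth$planted_region_bounds["end"]]
  }

  signature <- run_signature_pipeline(
    collection, seed_gene, alpha_corr = config$alpha_corr,
    alpha_de = config$alpha_de, require_sign = config$require_sign)

  profile <- group_mean_profile(methylation$beta, methylation$groups,
                                methylation$map)
  cumdiff <- cumulative_difference(profile, methylation$map)
  qvals <- per_cpg_test(methylation$beta, methylation$groups)
  regions <- detect_consistent_region(cumdiff, qvals,
                                      min_run = config$min_run,
                                      min_delta_pp = config$min_delta_pp,
                                      q_max = config$q_max)

  score_a <- promoter_score(methylation$beta, region_probes, methylation$map)
  shore_b <- methylation$second$map$probe_id[
    methylation$second$map$region_label != "island"]
  score_b <- promoter_score(methylation$second$beta, shore_b,
                            methylation$second$map)
  coupling <- methylation_expression_correlation(score_a,
                                                 methylation$seed_expression)
  cometh <- cross_promoter_correlation(score_a, score_b)
  auroc <- tumor_vs_normal_auroc(1 - score_a, methylation$groups)

  surv_res <- NULL
  if (!is.null(surv_tab)) {
    fit_marker <- cox_fit(surv_tab, "marker")
    km_labels <- dichotomize(surv_tab$marker, "median")
    km <- kaplan_meier(surv_tab$dfs_time, surv_tab$dfs_event, km_labels)
    lr <- logrank_test(surv_tab$dfs_time, surv_tab$dfs_event, km_labels)
    boot <- bootstrap_validate(
      surv_tab,
      survival::Surv(dfs_time, dfs_event) ~ marker + age + sex + smoking,
      B = config$bootstrap_B, seed = truth$rng_seed)
    surv_res <- list(cox = fit_marker, km = km, logrank = lr,
                     bootstrap = boot)
  }

  summary <- list(
    seed_gene = seed_gene,
    rng_seed = truth$rng_seed,
    thresholds = config[c("alpha_corr", "alpha_de", "require_sign",
                          "min_run", "min_delta_pp", "q_max",
                          "beta_threshold", "enet_mixing", "enet_folds",
                          "bootstrap_B")],
    signature_counts = as.list(signature$counts),
    n_region_calls = nrow(regions),
    region_calls = regions,
    coupling_r = coupling$r, coupling_p = coupling$p,
    comethylation_r = cometh$r, comethylation_p = cometh$p,
    auroc = auroc$auroc, auroc_p = auroc$p,
    cox_hr_marker = if (!is.null(surv_res))
      surv_res$cox$coefficients$hr[1] else NULL,
    logrank_p = if (!is.null(surv_res)) surv_res$logrank$p else NULL,
    bootstrap_corrected_c = if (!is.null(surv_res))
      surv_res$bootstrap$corrected else NULL
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(data.frame(stage = "de_filtered",
                         gene = signature$de_filtered),
              file.path(config$out_dir, "signature.tsv"))
    write_tsv(as.data.frame(cumdiff),
              file.path(config$out_dir, "cumulative_difference.tsv"))
    write_tsv(regions, file.path(config$out_dir, "region_calls.tsv"))
    if (!is.null(surv_res))
      write_tsv(surv_res$cox$coefficients,
                file.path(config$out_dir, "cox_coefficients.tsv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(signature = signature, profile = profile, cumdiff = cumdiff,
                 qvals = qvals, regions = regions, coupling = coupling,
                 comethylation = cometh, auroc = auroc,
                 survival = surv_res, truth = truth, summary = summary),
            class = "pipeline_result")
}
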