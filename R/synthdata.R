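#' Simulation configuration for the synthetic multi-omics generator
#'
#' Defines every knob of the linked expression / methylation / survival
#' generators. Defaults describe the reference study conditions used
#' throughout the test-suite: three cohorts per histology of 50 tumor and
#' 50 normal samples, 2000 genes with a 30-gene co-expression module
#' planted around a seed gene at population correlation 0.5 and a tumor
#' vs normal shift of 1.5 expression SD units; a 60-probe promoter map
#' (20 north-shore, 20 island, 20 south-shore CpGs) with a 5-CpG
#' hypomethylated run of 20 percentage points planted in the north shore;
#' inverse methylation-expression coupling of -0.5; cross-promoter
#' co-methylation of 0.8; and a proportional-hazards survival layer with
#' hazard ratio 2 per methylation-marker unit and ~40% uniform censoring.
#'
#' @param n_cohorts_per_histology cohorts simulated per histology tag.
#' @param n_samples_tumor,n_samples_normal samples per group per cohort.
#' @param n_genes genes per expression matrix.
#' @param module_size number of planted co-expressed genes (excluding the
#'   seed gene); must be smaller than `n_genes`.
#' @param target_module_r population Pearson correlation, in `[0, 1)`,
#'   between the seed gene and each module gene induced by a shared latent
#'   factor (0 disables the module).
#' @param de_effect tumor minus normal mean shift, in noise-SD units,
#'   applied to the seed and module genes (0 disables differential
#'   expression). Note that a nonzero shift adds mixture-induced
#'   correlation on top of `target_module_r`.
#' @param n_cpgs_island,n_cpgs_shore probes in the island and in each
#'   shore of the simulated promoter.
#' @param planted_region integer `c(start, length)`: position of the
#'   hypomethylated run inside the north shore (1-based probe index
#'   within the shore).
#' @param delta_meth tumor hypomethylation effect inside the planted
#'   region, in percentage points of methylation.
#' @param shore_beta,island_beta central beta level of shores (normal
#'   tissue) and island.
#' @param sigma_logit per-probe noise SD on the logit scale.
#' @param latent_loading loading of the shared per-sample latent factor
#'   on shore-probe logits; drives both within- and cross-promoter
#'   co-methylation. 0 makes probes independent.
#' @param coupling_rho target methylation-expression correlation in
#'   `(-1, 0]`.
#' @param comethylation_rho target cross-promoter methylation
#'   correlation in `[0, 1)`.
#' @param hazard_log_hr log hazard ratio per unit of the methylation
#'   marker.
#' @param confounder_effects named numeric log-HRs for `age`, `sex`,
#'   `smoking`.
#' @param censoring_rate target fraction of censored records in `[0, 1)`.
#' @param rng_seed single integer; all generators derive child seeds
#'   from it deterministically.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_cohorts_per_histology = 3,
                              n_samples_tumor = 50,
                              n_samples_normal = 50,
                              n_genes = 2000,
                              module_size = 30,
                              target_module_r = 0.5,
                              de_effect = 1.5,
                              n_cpgs_island = 20,
                              n_cpgs_shore = 20,
                              planted_region = c(start = 6, length = 5),
                              delta_meth = 20,
                              shore_beta = 0.70,
                              island_beta = 0.08,
                              sigma_logit = 0.45,
                              latent_loading = 0.4,
                              coupling_rho = -0.5,
                              comethylation_rho = 0.8,
                              hazard_log_hr = log(2),
                              confounder_effects = c(age = 0.02, sex = 0.3,
                                                     smoking = 0.4),
                              censoring_rate = 0.4,
                              rng_seed = 1L) {
  for (nm in c("n_cohorts_per_histology", "n_samples_tumor",
               "n_samples_normal", "n_genes", "module_size",
               "n_cpgs_island", "n_cpgs_shore"))
    stop_if_not_scalar_count(get(nm), nm)
  if (module_size >= n_genes) stop("module larger than genome")
  if (target_module_r < 0 || target_module_r >= 1)
    stop("'target_module_r' must lie in [0, 1)")
  if (de_effect < 0) stop("'de_effect' must be >= 0")
  planted_region <- as.integer(planted_region)
  if (length(planted_region) != 2L || any(planted_region < 1L))
    stop("'planted_region' must be c(start, length) with both >= 1")
  if (planted_region[1] + planted_region[2] - 1L > n_cpgs_shore)
    stop("'planted_region' must lie entirely within the shore probes")
  if (shore_beta <= 0 || shore_beta >= 1 || island_beta <= 0 || island_beta >= 1)
    stop("beta levels must lie strictly inside (0, 1)")
  if (shore_beta - delta_meth / 100 <= 0 || shore_beta - delta_meth / 100 >= 1)
    stop("'delta_meth' drives tumor beta outside (0, 1)")
  if (coupling_rho > 0 || coupling_rho <= -1)
    stop("'coupling_rho' must lie in (-1, 0]")
  if (comethylation_rho < 0 || comethylation_rho >= 1)
    stop("'comethylation_rho' must lie in [0, 1)")
  if (latent_loading < 0) stop("'latent_loading' must be >= 0")
  if (censoring_rate >= 1 || censoring_rate < 0)
    stop("'censoring_rate' must lie in [0, 1)")
  cfg <- list(
    n_cohorts_per_histology = as.integer(n_cohorts_per_histology),
    n_samples_tumor = as.integer(n_samples_tumor),
    n_samples_normal = as.integer(n_samples_normal),
    n_genes = as.integer(n_genes),
    module_size = as.integer(module_size),
    target_module_r = target_module_r,
    de_effect = de_effect,
    n_cpgs_island = as.integer(n_cpgs_island),
    n_cpgs_shore = as.integer(n_cpgs_shore),
    planted_region = stats::setNames(planted_region, c("start", "length")),
    delta_meth = delta_meth,
    shore_beta = shore_beta,
    island_beta = island_beta,
    sigma_logit = sigma_logit,
    latent_loading = latent_loading,
    coupling_rho = coupling_rho,
    comethylation_rho = comethylation_rho,
    hazard_log_hr = hazard_log_hr,
    confounder_effects = confounder_effects,
    censoring_rate = censoring_rate,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Null configuration: no planted structure
#'
#' Convenience wrapper setting `target_module_r = 0`, `de_effect = 0`,
#' `delta_meth = 0` and `hazard_log_hr = 0` (both module correlation and
#' the differential shift must be zeroed, since a tumor/normal mean shift
#' alone induces marginal co-expression through the group mixture).
#'
#' @param ... overrides passed on to [simulation_config()].
#' @export
null_config <- function(...) {
  simulation_config(target_module_r = 0, de_effect = 0, delta_meth = 0,
                    hazard_log_hr = 0, ...)
}

truth_new <- function(cfg) {
  genes <- gene_ids(cfg$n_genes)
  structure(list(
    seed_gene = genes[1L],
    planted_gene_ids = genes[seq_len(cfg$module_size) + 1L],
    planted_region_bounds = c(start = unname(cfg$planted_region["start"]),
                              end = unname(cfg$planted_region["start"] +
                                             cfg$planted_region["length"] - 1L)),
    true_coupling = cfg$coupling_rho,
    true_log_hr = cfg$hazard_log_hr,
    rng_seed = cfg$rng_seed
  ), class = "synthetic_truth")
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate linked expression cohorts with a planted co-expression module
#'
#' Simulates one log2-scale expression matrix per cohort for two
#' histologies. The seed gene and the `module_size` planted genes load on
#' a shared per-sample latent factor with loading `sqrt(target_module_r)`
#' and unit-variance residual noise, so the population correlation
#' between the seed and each module gene equals `target_module_r`; the
#' same genes receive a tumor-minus-normal mean shift of `de_effect`.
#' All other genes are independent standard normal noise.
#'
#' @param config a [simulation_config()].
#' @return A list with `collection` (a `cohort_collection`: named list of
#'   cohorts, each holding `expr` genes x samples, `histology`, `groups`)
#'   and `truth` (a `synthetic_truth`).
#' @export
generate_expression_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$rng_seed, 1L))
  truth <- truth_new(config)
  genes <- gene_ids(config$n_genes)
  module <- c(truth$seed_gene, truth$planted_gene_ids)
  histologies <- c("LUAD", "LUSC")
  nt <- config$n_samples_tumor; nn <- config$n_samples_normal
  n <- nt + nn
  load_f <- sqrt(config$target_module_r)
  load_e <- sqrt(1 - config$target_module_r)
  cohorts <- list()
  for (h in histologies) {
    for (k in seq_len(config$n_cohorts_per_histology)) {
      nm <- sprintf("%s_c%d", h, k)
      grp <- rep(c("tumor", "normal"), c(nt, nn))
      z <- as.numeric(grp == "tumor")
      f <- rnorm(n)
      expr <- matrix(rnorm(config$n_genes * n), nrow = config$n_genes,
                     dimnames = list(genes,
                                     sprintf("%s_s%03d", nm, seq_len(n))))
      idx <- match(module, genes)
      expr[idx, ] <- load_f * matrix(f, length(idx), n, byrow = TRUE) +
        load_e * expr[idx, , drop = FALSE] +
        config$de_effect * matrix(z, length(idx), n, byrow = TRUE)
      cohorts[[nm]] <- list(name = nm, histology = h, expr = expr,
                            groups = grp)
    }
  }
  collection <- structure(list(cohorts = cohorts), class = "cohort_collection")
  list(collection = collection, truth = truth)
}

build_cpg_map <- function(cfg, chrom = "chr6", pos0 = 30000L, id_offset = 0L) {
  n <- cfg$n_cpgs_shore * 2L + cfg$n_cpgs_island
  labels <- rep(c("north_shore", "island", "south_shore"),
                c(cfg$n_cpgs_shore, cfg$n_cpgs_island, cfg$n_cpgs_shore))
  data.frame(
    chrom = chrom,
    start = pos0 + seq_len(n) * 47L,
    end = pos0 + seq_len(n) * 47L + 1L,
    probe_id = sprintf("cg%08d", id_offset + seq_len(n)),
    region_label = labels,
    stringsAsFactors = FALSE
  ) |> as_cpg_map()
}

#' Generate promoter methylation beta matrices with a planted
#' hypomethylated shore run
#'
#' Betas are sampled on the logit scale (logit-normal): shores are
#' methylated (`shore_beta`) in normal tissue and the island is
#' unmethylated (`island_beta`) in both groups; tumor samples are
#' hypomethylated by `delta_meth` percentage points only inside the
#' planted north-shore run. Two promoters are simulated: shore logits of
#' both load on a shared per-sample latent factor so that their mean
#' promoter methylation correlates at `comethylation_rho`. A seed-gene
#' expression vector inversely coupled to the planted-region methylation
#' score at `coupling_rho` is emitted alongside.
#'
#' @param config a [simulation_config()].
#' @return list with `map` ([as_cpg_map()] data frame), `beta` (probes x
#'   samples), `groups`, `second` (second promoter: `map`, `beta`),
#'   `seed_expression` (named numeric, one value per sample) and `truth`.
#' @export
generate_methylation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(child_seed(config$rng_seed, 2L))
  truth <- truth_new(config)
  nt <- config$n_samples_tumor; nn <- config$n_samples_normal
  n <- nt + nn
  groups <- rep(c("tumor", "normal"), c(nt, nn))
  samples <- sprintf("meth_s%03d", seq_len(n))

  map_a <- build_cpg_map(config, chrom = "chr6", pos0 = 30000L)
  map_b <- build_cpg_map(config, chrom = "chr11", pos0 = 117000L,
                         id_offset = 10000L)
  region <- truth$planted_region_bounds  # indices within the north shore,
  # which leads the map, so they are also global probe indices

  rho <- config$comethylation_rho
  u <- rnorm(n)
  lat_a <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(n)
  lat_b <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(n)
  lambda <- config$latent_loading  # latent loading on shore logits

  draw_promoter <- function(map, latent, planted) {
    p <- nrow(map)
    mu <- ifelse(map$region_label == "island",
                 qlogis(config$island_beta), qlogis(config$shore_beta))
    mu <- matrix(mu, p, n)
    if (planted && config$delta_meth > 0) {
      tum <- which(groups == "tumor")
      mu[region["start"]:region["end"], tum] <-
        qlogis(config$shore_beta - config$delta_meth / 100)
    }
    shore <- map$region_label != "island"
    lat <- outer(as.numeric(shore) * lambda, latent)
    beta <- plogis(mu + lat + matrix(rnorm(p * n, sd = config$sigma_logit),
                                     p, n))
    dimnames(beta) <- list(map$probe_id, samples)
    beta
  }

  beta_a <- draw_promoter(map_a, lat_a, planted = TRUE)
  beta_b <- draw_promoter(map_b, lat_b, planted = FALSE)

  score <- colMeans(beta_a[region["start"]:region["end"], , drop = FALSE])
  rho_c <- config$coupling_rho
  z <- as.numeric(scale(score))
  seed_expr <- rho_c * z + sqrt(1 - rho_c^2) * rnorm(n)
  names(seed_expr) <- samples

  list(map = map_a, beta = beta_a, groups = groups,
       second = list(map = map_b, beta = beta_b),
       seed_expression = seed_expr, truth = truth)
}

#' Generate DFS and OS survival outcomes under a proportional-hazards
#' model
#'
#' Event times are exponential with rate `lambda0 * exp(lp)` where
#' `lp = hazard_log_hr * marker + confounder_effects . (age, sex,
#' smoking)`. Censoring is independent uniform on `(0, cmax)` with `cmax`
#' solved numerically so the expected censored fraction equals
#' `censoring_rate`; `censoring_rate = 0` yields all-event data.
#'
#' @param covariates data frame with columns `sample_id`, `marker`
#'   (methylation status or continuous methylation level), `age`, `sex`,
#'   `smoking`.
#' @param config a [simulation_config()].
#' @param baseline_rate_dfs,baseline_rate_os baseline hazards per month.
#' @return a `survival_table` data frame with `dfs_time`, `dfs_event`,
#'   `os_time`, `os_event` plus the covariate columns.
#' @export
generate_survival <- function(covariates, config,
                              baseline_rate_dfs = 0.02,
                              baseline_rate_os = 0.012) {
  stopifnot(inherits(config, "simulation_config"))
  need <- c("marker", "age", "sex", "smoking")
  if (!all(need %in% names(covariates)))
    stop("covariates must include: ", paste(need, collapse = ", "))
  set.seed(child_seed(config$rng_seed, 3L))
  n <- nrow(covariates)
  ce <- config$confounder_effects
  lp <- config$hazard_log_hr * covariates$marker +
    ce[["age"]] * covariates$age + ce[["sex"]] * covariates$sex +
    ce[["smoking"]] * covariates$smoking
  lp <- lp - mean(lp)  # center: baseline hazard absorbs the constant

  censor <- function(t) {
    if (config$censoring_rate == 0)
      return(list(time = t, event = rep(1L, n)))
    f <- function(cmax) mean(pmin(t / cmax, 1)) - config$censoring_rate
    cmax <- uniroot(f, lower = min(t) * 1e-6, upper = max(t) * 1e6)$root
    cens <- runif(n, 0, cmax)
    list(time = pmin(t, cens), event = as.integer(t <= cens))
  }

  t_dfs <- rexp(n, rate = baseline_rate_dfs * exp(lp))
  t_os <- rexp(n, rate = baseline_rate_os * exp(lp))
  dfs <- censor(t_dfs)
  os <- censor(t_os)

  out <- data.frame(
    sample_id = covariates$sample_id %||% sprintf("surv_s%03d", seq_len(n)),
    dfs_time = dfs$time, dfs_event = dfs$event,
    os_time = os$time, os_event = os$event,
    covariates[setdiff(names(covariates), "sample_id")],
    stringsAsFactors = FALSE
  )
  class(out) <- c("survival_table", "data.frame")
  out
}
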