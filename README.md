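# shoresig

Tools for discovering and validating epigenetically co-regulated gene
signatures in tumor cohorts. The package implements, as reusable tested
components, the computational chain by which such signatures are found:

1. **Consensus co-expression screen** — for a seed gene, every other
   gene is tested for correlation in each of several expression cohorts
   (Pearson r, p from the t-transform, Benjamini–Hochberg q). A gene
   survives only if `q ≤ α` with consistent sign in *every* cohort of a
   histology; histology-level sets are intersected and filtered by a
   tumor-vs-normal Mann–Whitney test, yielding the final signature.
2. **Shore hypomethylation analysis** — over ordered promoter CpGs
   (north shore → island → south shore), the per-probe group difference
   in percent methylation, `δᵢ = m̄ᵢ(normal) − m̄ᵢ(tumor)`, is
   accumulated in map order, `Cᵢ = Σ_{j≤i} δⱼ`. Steeply rising segments
   of the cumulative curve mark consistent tumor hypomethylation; calls
   are maximal runs of ≥ 5 consecutive CpGs with `δ ≥ 5` percentage
   points and Mann–Whitney `q ≤ 0.05` each. Betas classify as
   methylated at the conventional `β ≥ 0.5`.
3. **Integration** — promoter methylation scores (mean β over an
   interval), methylation–expression inverse correlation,
   cross-promoter co-methylation, and tumor/normal AUROC by mid-rank
   pair counting with the Mann–Whitney p-value.
4. **Prognosis** — Kaplan–Meier/log-rank, Cox proportional-hazards fits
   adjusted for age, sex and smoking (Efron ties), elastic-net
   penalized Cox selection of prognostic CpGs with unpenalized refit,
   Harrell bootstrap optimism-corrected concordance, and nested
   likelihood-ratio tests for two-marker models.
5. **Synthetic multi-omics generator** — seeded, with recorded ground
   truth: planted co-expression modules, a planted hypomethylated shore
   run beside an unmethylated island, inverse methylation–expression
   coupling, cross-promoter co-methylation, and exponential
   proportional-hazards survival. Every pipeline stage is testable
   without external cohort data.

See `vignettes/shoresig-methods.Rmd` for the full methodological
account and design rationale.

## Worked example

```r
library(shoresig)

cfg <- simulation_config(n_samples_tumor = 40, n_samples_normal = 40,
                         rng_seed = 7)

## co-expression cascade on 6 simulated cohorts
sim <- generate_expression_cohorts(cfg)
run_signature_pipeline(sim$collection, sim$truth$seed_gene)
#> Consensus co-expression signature (seed gene: g00001 )
#>   LUAD consensus: 30 genes
#>   LUSC consensus: 30 genes
#>   common: 30 genes
#>   DE-filtered: 30 genes

## promoter methylation: cumulative curve and region call
m  <- generate_methylation(cfg)
cd <- cumulative_difference(group_mean_profile(m$beta, m$groups, m$map), m$map)
detect_consistent_region(cd, per_cpg_test(m$beta, m$groups))
#>   start end probe_start  probe_end run_length mean_delta regions_spanned
#> 1     6  10  cg00000006 cg00000010          5   18.71068     north_shore

## methylation-expression coupling and tumor discrimination
b  <- m$truth$planted_region_bounds
sc <- promoter_score(m$beta, m$map$probe_id[b["start"]:b["end"]], m$map)
methylation_expression_correlation(sc, m$seed_expression)
#> coupling r = -0.448 (p = 3.14e-05, n = 80)
tumor_vs_normal_auroc(1 - sc, m$groups)
#> AUROC (1 - score) tumor vs normal = 0.894

## prognosis: planted hazard ratio of 2 on a continuous marker
set.seed(7)
covs <- data.frame(sample_id = sprintf("s%03d", 1:300), marker = rnorm(300),
                   age = round(rnorm(300, 65, 8)), sex = rbinom(300, 1, .5),
                   smoking = rbinom(300, 1, .6))
cox_fit(generate_survival(covs, cfg), "marker")
#> Cox fit (DFS, 300 samples, 177 events)
#>      term   coef      se   hr ci_lo ci_hi        p
#> 1  marker 0.7114 0.08961 2.04  1.71  2.43 2.04e-15
#> ...
```

The 30 recovered genes are exactly the planted module; the region call
matches the planted 5-CpG run (probes 6–10, ≈ 20 percentage points of
tumor hypomethylation); the Cox hazard ratio of 2.04 (CI 1.71–2.43)
recovers the planted HR = 2.

The whole chain can also be driven from one configuration:

```r
res <- run_pipeline(run_config(sim = cfg, out_dir = "out"))
```

which writes per-stage TSVs and a `summary.json` recording every
threshold used.

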