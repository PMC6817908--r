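---
title: "Methods: consensus co-expression screening and shore hypomethylation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus co-expression screening and shore hypomethylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoresig)
```

## The scientific problem

Oncogenes can be switched on in tumors by *loss* of DNA methylation in
their promoters. In non-small cell lung cancer, pairs of functionally
related genes have been found to be jointly over-expressed and jointly
hypomethylated — a pattern discovered by (i) screening public expression
cohorts for genes consistently co-expressed with a seed gene, and then
(ii) examining promoter methylation of candidate partners on
Infinium-450k-style arrays, where probes tile an unmethylated CpG island
and its flanking methylated shores. `shoresig` packages that discovery
chain as reusable, tested components, together with a seeded synthetic
multi-omics generator so each stage can be validated against planted
ground truth.

## The consensus co-expression cascade

For each cohort, every gene is correlated with the seed gene (Pearson by
default; Spearman available). P-values come from the t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$, with Benjamini–Hochberg adjustment across
all testable genes of that cohort. A gene enters a histology's consensus
only if $q \le \alpha$ in *every* cohort of that histology with a
consistent (by default positive) correlation sign. The two
histology-level sets are intersected, and the common signature is
filtered by a tumor-vs-normal two-sided Mann–Whitney test in a
designated cohort, with BH adjustment restricted to the common set —
mirroring the order of the original cascade. Each stage's output is a
subset of its input, so the per-stage counts are monotone.

Two defaults deserve comment because the procedure is often described
only as "significantly co-expressed in all databases":

* the per-cohort significance rule is FDR-adjusted $q \le 0.05$, chosen
  because thousands of genes are screened per cohort;
* the sign constraint defaults to positive correlation, the pattern of
  interest for co-regulated partners; both are arguments, not constants.

Spearman p-values use the same t-transform on the rank correlation (a
large-sample approximation) so the screen stays vectorised over
thousands of genes.

## The cumulative-difference methylation statistic

Probes are ordered along the promoter (north shore → island → south
shore). For each probe the group difference in mean percent methylation
is computed with the orientation `delta = normal − tumor`, so tumor
hypomethylation is positive; the legend convention is not universal, so
the package fixes and documents this sign. The running sum of `delta` in
map order is the cumulative-difference curve: consistently hypomethylated
shores appear as steep rising segments, while the island — unmethylated
in both groups — traces a flat segment.

"Steep slope" is operationalised as a run criterion rather than a
derivative threshold: a region call is a maximal run of at least
`min_run = 5` consecutive probes, each with `delta ≥ 5` percentage
points and Mann–Whitney BH-adjusted `q ≤ 0.05`. The per-CpG test is the
Mann–Whitney U (exact when both groups have ≤ 8 samples and no ties,
mid-rank normal approximation with continuity correction otherwise); a
nonparametric test avoids having to model beta distributions. All three
run parameters are configurable; the default of 5 consecutive CpGs
matches the granularity at which such regions are typically reported.

Classification of individual beta values uses the conventional 0.5
threshold, with the boundary value assigned to the methylated class so
that both classes remain attainable under any data; the threshold is an
argument.

## Integration statistics

The promoter methylation score is the unweighted mean beta over a stated
probe interval (median available); correlation of the score with
expression (methylation–expression coupling) and between two promoters'
scores (co-methylation) uses the same correlation machinery as the
screen. Tumor/normal discrimination is summarised by the AUROC, computed
from mid-ranks — algebraically identical to exhaustive pair counting
with half credit for ties — with its p-value from the equivalent
Mann–Whitney test. A DeLong-style confidence interval is deliberately
out of scope; the U-test p is what is reported.

## The prognostic layer

Kaplan–Meier curves, the log-rank test, and Cox proportional-hazards
fits are delegated to the `survival` package; ties use the Efron
approximation (the accepted default). Dichotomization supports mean,
median and fixed-beta-threshold rules, boundary up. Elastic-net
penalized Cox selection over candidate CpGs uses `glmnet` with mixing
parameter 0.5 and penalty chosen by 10-fold cross-validated partial
likelihood at the one-standard-error rule — none of these are canonical
in the source procedure, so all are exposed as arguments and recorded in
run summaries; selected CpGs are refit unpenalized together with the
confounders (age, sex, smoking). Internal validation is Harrell's
bootstrap optimism correction of the concordance index (the validation
metric itself is a package choice, as bootstrap validation is often
reported without naming one). Whether a second marker adds prognostic
information is assessed by the nested likelihood-ratio test,
$2\Delta\ell$ on the parameter-count difference; the self-test is
exactly zero by construction.

"Continuous survival analysis" of a methylation marker is rendered as
Cox-model-predicted survival curves over the marker's observed range at
mean confounder levels (`cox_predicted_survival()`); the construction is
not standardised in the literature, so this interpretation is documented
here as the package's own.

## The synthetic generator: what it emulates

The generator's defaults define the reference study conditions used by
the test-suite:

* **Expression**: 3 cohorts per histology, 50 tumor + 50 normal samples
  each, 2000 genes. The seed gene and 30 module genes share one latent
  factor with loading $\sqrt{r}$ (target $r = 0.5$), giving closed-form
  control of the planted correlation, plus a tumor shift of 1.5 noise-SD
  units. A tumor/normal mean shift *by itself* induces marginal
  correlation through the group mixture, so the null configuration
  (`null_config()`) zeroes both the module correlation and the shift.
* **Methylation**: a 60-probe promoter (20/20/20), logit-normal betas —
  chosen over a Beta law because additive effects and latent-factor
  coupling are simple to impose on the logit scale, and only the
  marginal location/spread matter downstream. Shores sit at beta 0.70
  (normal), the island at 0.08; tumors lose 20 percentage points only
  inside a planted 5-CpG north-shore run. Per-probe logit noise is 0.45
  and a shared per-sample latent factor loads on all shore probes at
  0.4; the pair was chosen to keep per-CpG testing well-powered at
  40 + 40 samples while still producing realistic within- and
  cross-promoter co-methylation (the cross-promoter latent correlation
  is set to 0.8; score-level attenuation from probe noise, the logistic
  transform and the planted group structure brings the observed
  correlation to roughly the mid-0.7s, which is the intended "very
  strong" regime).
* **Coupling**: seed-gene expression is regressed on the planted-region
  methylation score with slope set to hit the target correlation (−0.5),
  claiming association, not mechanism.
* **Survival**: exponential proportional hazards with linear predictor
  `log(2)·marker + 0.02·age + 0.3·sex + 0.4·smoking`, uniform
  independent censoring with its upper bound solved numerically to hit
  the target censoring fraction (0.4, i.e. ~60% events). The planted
  marker may be binary methylation status or a standardized continuous
  methylation level; hazard-ratio recovery experiments use the
  continuous form, matching the use of continuous methylation in Cox
  models and giving the marker unit variance.

One global integer seed drives everything; each generator derives a
fixed child seed from it, so a single integer reproduces the full study.

## Monte-Carlo sizes and numerical choices

Calibration checks (log-rank and nested-LRT type-I error) use 1000
replicates in the test-suite and 400 in the acceptance script — sizes
chosen so the Monte-Carlo standard error of a 5% rejection rate is small
against the calibration bands being asserted. Recovery checks use
50/100 seeds at the reference sample sizes quoted above. Stochastic
point estimates (AUROC, coupling, co-methylation, hazard ratio) are
averaged over 10–25 independent replicates. Ties in expression or beta
ranks use mid-ranks; degenerate inputs (zero-variance genes, all-missing
probes or samples, constant markers) are flagged or rejected rather than
silently propagated; probes with under 50% group coverage are excluded
from profiles and logged.

## What passing tests do and do not show

The generator reproduces the *statistical structure* the pipeline
exploits — multi-cohort co-expression, tumor-restricted shore
hypomethylation next to an unmethylated island, inverse coupling,
cross-promoter correlation, proportional hazards — but not the
technical texture of real arrays: no probe-chemistry artefacts, batch
effects, copy-number confounding, cell-type composition, or non-PH
hazards; DFS and OS are drawn independently rather than jointly.
Passing the planted-truth tests therefore demonstrates correctness of
the computations and sensible operating characteristics at realistic
sizes, not performance guarantees on any particular clinical cohort.
Quantitative findings reported for real cohorts (gene counts of a
published cascade, AUROCs, published correlation coefficients and
p-values) depend on data that is not packaged and are not reproduced
here.
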