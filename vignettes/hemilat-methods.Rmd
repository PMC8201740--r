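---
title: "Hemispheric laterality analysis: models, conventions and validation"
author: "hemilat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric laterality analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemilat)
```

## The problem

Chronic social defeat stress splits mice into two behavioral phenotypes:
*susceptible* animals develop social avoidance, *resilient* animals do not.
The two hemispheres of the medial prefrontal cortex (mPFC) respond to stress
differently, and the question this package addresses is molecular: **which
genes are expressed asymmetrically between the left and right mPFC, and does
that asymmetry track stress susceptibility?** The pipeline covers the whole
chain — behavioral classification, bilateral expression preprocessing,
hemisphere-paired differential expression, per-gene laterality scoring, and
gene-set lateralization — together with a synthetic-data generator so that
every stage can be validated against a known ground truth.

## Behavioral classification

The sociability index (SI, also called the interaction ratio) is the time a
mouse spends in the interaction zone with a social target present divided by
the time spent there with the target absent. Stressed mice with SI above the
exclusion band are resilient, below it susceptible; non-stressed mice are
controls. The band (default the closed interval $[0.9, 1.1]$) removes animals
whose susceptible and resilient traits overlap.

Two conventions were genuinely open and are fixed as follows:

* **Band endpoints.** An SI of exactly 0.9 or 1.1 is *excluded* (closed
  band). The simple ">1 resilient, <1 susceptible" rule leaves SI = 1
  unassigned; the band subsumes it, so classification is total.
* **Raw times.** The SI is computed from raw zone seconds, with no
  normalization of the two assay phases; a zero no-target time is an error
  rather than an infinite ratio.

The companion endpoints follow their standard definitions: sucrose preference
is $100 \cdot \text{sucrose} / (\text{sucrose} + \text{water})$ percent, and
forced-swim immobility is summarized by the onset latency (referenced to the
start of the assay, since the tracking clock starts there) and the total
immobility inside the scored window, by default the last 4 min of a 6 min
assay.

## Expression model and moderated statistics

Normalized log2 intensities are modeled per gene with a cell-means linear
model over the six conditions (3 groups $\times$ 2 hemispheres),

$$x_{gs} = \mu_{g,\,\text{cell}(s)} + \varepsilon_{gs}, \qquad
  \varepsilon_{gs} \sim N(0, \sigma_g^2),$$

fitted by least squares: condition means plus one pooled residual variance
$s_g^2$ on $d_g = n - 6$ degrees of freedom. Replicates enter the model
individually (not as condition means), so $d_g = 6(r-1)$ in a balanced
design with $r$ replicates per cell.

Gene-wise variances are moderated by an empirical-Bayes hierarchy,
$\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$. The prior $(d_0, s_0^2)$ is
estimated by moment-matching the distribution of $\log s_g^2$ against its
closed digamma/trigamma form; when the spread of $\log s_g^2$ does not
exceed its sampling floor the estimator returns $d_0 = \infty$ (all
variances shrink completely to $s_0^2$, and the reference distribution
becomes normal). A maximum-likelihood refinement is deliberately out of
scope — the moment estimator is accurate at array scale, and the test suite
verifies it against an independent reference implementation.

Each of the **seven pairwise contrasts** — the three within-group
left-vs-right comparisons and four group-vs-control comparisons within
hemisphere — is tested with the moderated t,

$$\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
  t_g = \frac{\Delta_g}{\tilde{s}_g\sqrt{1/n_A + 1/n_B}},$$

on $d_0 + d_g$ degrees of freedom. At $d_0 = 0$ this is exactly the
classical pooled-variance t (verified to $10^{-10}$ against an independently
coded oracle). Benjamini–Hochberg adjustment is applied **within each
contrast independently** — the default behavior of the standard moderated-t
workflow — and significance means FDR < 0.05.

## Laterality scoring

The laterality score of a gene in a group is
$\log_2 L/R = \bar{x}_L - \bar{x}_R$, the difference of condition means on
the log2 scale (not the mean of per-replicate ratios — the score is exactly
the left-vs-right contrast estimate of the linear model). Positive scores
are left-dominant. The screened gene list is the **union** of the three
within-group left-vs-right screens at FDR < 0.05; this reading makes the
three-set Venn partition and the screened-list size mutually consistent.
Ranking is descending by the susceptible-group score, with ties broken
lexicographically by gene id for reproducibility. Housekeeping genes (Actb,
Gapdh, B2m by default) serve as a negative control: their left-vs-right raw
p-values should all sit above 0.05 in every group, otherwise unequal RNA
input is suspected.

## Gene-set lateralization

For a gene set, each member contributes its log2 fold change versus
same-hemisphere controls (left and right separately). The set-level test is
a classical pooled-variance two-sample t between the left and right lists
with $df = 2n - 2$, where $n$ is the number of members with data. This
treats **member genes as the sampling unit**. Genes are not independent
observations, so these p-values overstate certainty; the convention is
reproduced deliberately because it is the convention of the set-level
box-plot statistics this module mirrors (a paired-by-gene design would give
$df = n - 1$, which does not match that convention). Interpret set-level
p-values comparatively, not literally.

## Behavioral statistics battery

* **Student's t** — pooled variance, two-tailed; paired data use the
  one-sample t on differences. Fully degenerate spread with equal means
  returns $t = 0$, $p = 1$ rather than an error, so constant synthetic
  edge cases flow through.
* **Mann–Whitney** — the statistic T is the rank sum of the *smaller* group
  (ties in size resolve to the first argument). The p-value is exact by
  enumeration of rank assignments when the smaller group has at most 8
  observations, otherwise a tie-corrected normal approximation with
  continuity correction. The two diverge in the extreme tails at very small
  n, where the exact distribution is coarse (steps of $\sim 1/6$ at
  $n_1 = n_2 = 2$); no continuous approximation can track that within 0.01,
  which is why the exact route is the default whenever it is feasible.
* **Kruskal–Wallis** — tie-corrected H on $k - 1$ df; the post hoc is a
  Tukey-type comparison of mean ranks against the studentized range (the
  behavior of the originating stats package's "Tukey test" on ranks).
* **Two-way ANOVA** — sequential (Type-I) sums of squares on balanced data,
  Type-II on unbalanced. One analysis convention worth flagging: hemisphere
  is treated as a between factor here even though left and right come from
  the same animals, reproducing the printed analyses; a repeated-measures
  design over hemisphere is the statistically stricter alternative.
* **Two-way repeated-measures ANOVA** — mixed design; the between factor is
  tested against subjects-within-groups, the within factor and interaction
  against the within $\times$ subjects residual. The stratum sums of
  squares are returned and conserve the total exactly.
* **Post hoc** — run only when a main effect or interaction reaches
  p < 0.05 (the originating package's trigger). Simple-effect pairwise
  comparisons use the appropriate error stratum and are Holm–Šidák
  adjusted within each comparison family:
  $p_{(i)} \mapsto 1 - (1 - p_{(i)})^{m - i + 1}$, monotonized.

## The synthetic generator

`sim_config()` fixes the study conditions the pipeline is validated under:

| parameter | default | meaning |
|---|---|---|
| design | 3 groups × 2 hemispheres × 3 replicates | balanced bilateral arrays |
| `n_genes` | 2000 | array size (scaled for fast validation) |
| `n_lateral_genes` | 100 | genes planted with susceptible-group laterality |
| `lateral_effect_range` | [1, 2] | planted $|\log_2 L/R|$, uniform |
| `variance_prior_df`, `variance_prior_scale` | 4, 0.05 | $\sigma_g^2 \sim s_0^2 d_0/\chi^2_{d_0}$ |
| `baseline_mean_range` | [6, 12] | per-gene baseline log2 intensity |
| `si_distributions` | 1.5/1.5/0.8 (sd 0.4/0.4/0.3) | group SI means match the cohort averages of the emulated design |
| `detection_fail_rate` | 0.02 | Bernoulli per probe × sample |

Choices that merit a word:

* **Symmetric effect placement.** A planted gene receives $+\delta/2$ on the
  left and $-\delta/2$ on the right, so the true $\log_2 L/R$ equals
  $\delta$ exactly and recovery targets are analytic.
* **SI simulation.** SI is drawn from the group's normal distribution
  truncated at zero and multiplied into a fixed 50 s no-target time; this
  guarantees positive times and makes the zero-sd case exact. The
  truncation bias is negligible at the configured means (≥ 2.7 sd from
  zero).
* **Detection failures** are independent Bernoulli per cell; failed cells
  draw their p-value uniformly above 0.05, detected cells below. No
  structure across probes or samples is modeled.
* **SI sd values** (0.4/0.4/0.3) are not printed anywhere in the emulated
  design and were chosen once as a realistic spread for defeat cohorts —
  wide enough that stressed simulants straddle the exclusion band.
* Replicates are exchangeable technical draws; the RNA pooling that
  precedes arrays in the emulated design is not modeled explicitly, which
  is one reason simulated replicate noise should not be read as biological
  variance.

What the generator does **not** emulate: gene–gene correlation, batch and
chip effects, probe-level artifacts, background correction, and
intensity-dependent variance trends. Passing recovery tests on this
generator therefore demonstrates correctness of the statistical machinery
under its own assumptions, not robustness to real-array pathologies.

## Numerical choices and degenerate inputs

* Quantile normalization maps every sample to the mean of the row-sorted
  columns (ties averaged); it is idempotent and rank-preserving, and a
  single-sample matrix is a warned no-op.
* The detection filter's default policy excludes a gene when more than half
  the replicates of any condition are undetected ("majority"); "any" and
  "all" are available because the underlying one-sentence rule is genuinely
  ambiguous. Exact reproduction of a historical gene list can depend on
  this choice and on the normalization variant.
* Zero residual variance with a zero mean difference gives $t = 0$; the
  empirical-Bayes prior makes this configuration vanishingly rare on real
  data.
* `estimate_eb_prior()` drops zero variances with a warning and errors only
  when nothing positive remains.
* All randomized functions take their seed from `sim_config()`; identical
  configurations are byte-identical on re-run, and the RNG state of the
  caller is restored.

## Validation scale and known limitations

The shipped validation runs at deliberate desk scale: null calibration uses
5000 genes × 20 seeds (KS uniformity of raw p per contrast, and FDR calls
inside the binomial envelope of the global null), recovery uses 100 planted
genes of 2000 over 20 seeds, and prior recovery uses one 20000-gene study.
At the recovery conditions ($\delta = 1$, prior (4, 0.05), triplicates) the
susceptible-screen sensitivity computed by `scripts/acceptance.R` is about
0.79 with empirical FDR near 0.05 and planted-effect bias under 2% — the
power ceiling of the moderated t itself under that variance hierarchy
(heavy-tailed at $d_0 = 4$: roughly a quarter of genes draw
$\sigma^2 > 0.1$, where a one-unit shift at three replicates is hard to
reach genome-wide significance for). Set-level and dataset-level headline
counts from the original deposited arrays (GEO accession GSE114224) are not
recomputed here; the reader pointed at that accession can feed the series
matrix through `read_series_matrix()` and the same pipeline.
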