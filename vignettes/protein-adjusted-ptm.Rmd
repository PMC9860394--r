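---
title: "Protein-adjusted differential abundance of PTMs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-adjusted differential abundance of PTMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ptmquant)
library(dplyr)
```

## The problem

Bottom-up proteomics quantifies a posttranslational modification (PTM) site
through the intensities of its modified peptide ions, usually acquired after
biochemical enrichment. A change in those intensities between conditions
confounds two biological signals: a change in the modification itself, and a
change in the overall abundance of the parent protein. Testing the raw PTM
fold change `Δ_PTM = μ*_i − μ*_i'` therefore produces false positives
whenever the protein moves, and false negatives whenever a protein change
masks a genuine modification change. The quantity of biological interest is
the *adjusted* change

```
Δ_adj = (μ*_i − μ_i) − (μ*_i' − μ_i') = Δ_PTM − Δ_protein,
```

the modification change beyond the overall protein change, estimated from a
separate global profiling acquisition of the unenriched proteome.

## The model

The pipeline has three stages, each per target (a PTM site, or a protein).

**Summarization.** The log2 intensities of a target's features (peptide
ions) in each run are collapsed to one value per run by Tukey's two-way
median polish (overall + feature + run effects; run summary = overall
effect + run's column effect). Median polish is robust to outlying feature
observations and tolerates missing cells: the run medians simply ignore
them, so a run summary exists whenever at least one feature is observed in
that run. A log-sum alternative (`log2(sum(2^y))`) is provided because the
ratio-based baseline methods are defined on it. Runs with no observed
feature yield no summary — they are never zero-filled.

**Modeling.** Run summaries of each target are modeled by a one-way
fixed-effects model `ŷ_ij = μ_i + ε_ij, ε ~ N(0, σ²)` for label-free group
comparisons, estimated by least squares with a pooled residual variance and
`df = Σ_i (J_i − 1)` (equal to `I(J−1)` in balanced designs). Multi-mixture
TMT experiments add a random mixture intercept, estimated by REML, with
contrast degrees of freedom from the Satterthwaite approximation. When a
model is not estimable for a target — a single mixture, or non-convergence —
the fit falls down a ladder (`tmt_mixed → oneway`), recorded in the fit's
`design` field so that no target silently changes model class.

**Adjustment.** For a contrast `(i, i')`, the PTM and protein inferences
are combined as

```
Δ̂_adj  = Δ̂_PTM − Δ̂_protein
SE_adj  = sqrt(SE_PTM² + SE_protein²)
df_adj  = (SE_PTM² + SE_protein²)² / (SE_PTM⁴/df_PTM + SE_protein⁴/df_protein)
```

The SEs add in quadrature because the enriched and global acquisitions are
independent experiments; the Satterthwaite df always lies between
`min(df_PTM, df_protein)` and their sum. Sites without global profiling
information cannot be adjusted; they are passed through as unadjusted PTM
tests with `issue = "no_protein_match"` rather than dropped, and the
results table states which null hypothesis each row actually tests.
Benjamini–Hochberg correction is applied afterwards.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `summarization` | `median_polish` | robust to outlier features; log-sum is kept for the baselines |
| median-polish iterations | 10, tol 1e-4 (relative change in total absolute residual) | common practice; the polish converges in a handful of sweeps on feature matrices |
| `moderate` | `FALSE` | the headline adjusted analysis is unmoderated; empirical-Bayes moderation (`limma`-style scaled inverse-chi-square prior) is available and is always used inside the `limma_*` baselines |
| `impute` | `"off"` | AFT imputation treats missingness as left-censoring; that assumption is defensible for low-abundance protein features but rarely for enriched features, so imputation is opt-in and restricted to protein matrices |
| variance floor | 1e-12 | residual variances below it are treated as exactly zero, with a degenerate-t convention (p = 0 for a non-zero estimate, with a warning) |
| negative REML variance components | truncated at 0 | standard convention |
| BH family | per contrast | matches how per-comparison results are read; adjusted and passed-through rows share one family because they appear in one table (a `global` family is available) |

## What the simulator emulates — and what it does not

`simulate_ptm()` generates the two benchmark designs used throughout the
package. Each of `n_proteins` (default 1000) proteins carries one PTM site.
Per table, a protein log2 baseline is drawn from `N(25, 2²)` and fixed
per-feature offsets from `N(0, 1)`; these constants only set the intensity
scale — every reported metric is a difference, so they affect none of the
benchmark quantities. The four truth classes (250 each at the default
size) encode the confounding structure: directly differential PTMs,
differential PTMs fully masked by an opposite protein change, flat nulls,
and nulls whose apparent PTM change is entirely protein-driven. All
differential PTMs use an expected log2 fold change of 0.75, feature noise
is iid Gaussian with `σ² ∈ {0.2, 0.3}`, and the designs span 2–4 conditions
and 2–10 replicates. The clean preset (`sim1`) uses 10 modified and 10
unmodified features and no missingness; the realistic preset (`sim2`) uses
2 modified features and deletes 20% of observations completely at random,
independently in the enriched and global tables.

The simulator deliberately does **not** emulate: correlated features,
intensity-dependent (left-censored) missingness, outlier contamination,
shared peptides across proteins, multi-site occupancy interplay, or
between-run normalization artifacts. Passing benchmarks on these data
therefore shows that the statistical machinery is correct and calibrated
under its own assumptions — not that every real acquisition satisfies
those assumptions.

The masked class is implemented as observed-PTM flat with the protein
shifted by `−effect` (so the adjusted change is `+effect`); the sign is
configurable (`masked_sign`) since "masked by a protein change" admits
either orientation.

## Numerical choices

* Median polish uses median sweeps that ignore `NA` cells; 1-row and
  1-column matrices short-circuit to the obvious summaries.
* One-way fits are computed in closed form (group means, pooled SS),
  vectorized over thousands of targets; the test suite cross-checks them
  against `lm()`-style pooled t-tests to 1e-10.
* Mixed fits use `lmerTest` (REML; Satterthwaite df from the information
  matrix by numerical differentiation). A condition observed in a single
  mixture remains estimable with visibly reduced df.
* The power solver inverts the design relation by bisection (tolerance
  1e-10). The relation couples the per-comparison level α to the Type II
  error β through the FDR target, so both "solve for power" and "solve for
  q" are root-finding problems on the unit interval; when no interior root
  exists the boundary is returned with `boundary = TRUE`.
* The unequal-allocation power surface replaces the balanced variance
  `2(σ²_PTM + σ²_protein)/J` by `2σ²_PTM/J_PTM + 2σ²_protein/J_protein`,
  the natural generalization of the pooled-SE formula when the enriched
  and global designs differ in size.
* Ambiguous site localization (a peptide matching several positions or
  accessions) is an error by default, with `keep_first = TRUE` as the
  explicit opt-out: silent resolution of ambiguity is how sites get
  mislabeled.

## Problem sizes used by the shipped benchmarks

The packaged benchmark scripts and tests run the clean design at its full
scale (1000 proteins, 2 conditions, 10 replicates) and the noisy design
over its full 24-configuration grid for the data-loss accounting; the
fold-change IQR comparison uses three design settings at both noise levels
(six datasets), which is ample to pin down the direction and approximate
size of the effect while keeping a full run in the minutes range on a
single core.

## A worked sketch

```{r example}
cfg <- sim_config("sim2", n_proteins = 60, n_replicates = 5, seed = 42)
sim <- simulate_ptm(cfg)
res <- ptm_differential(sim$enriched, sim$global,
                        contrasts = list(c("C2", "C1")))
glance(res)
evaluate_calls(res, sim$truth, alpha = 0.05)
```

Planning a follow-up experiment from anticipated variances (0.45 for the
PTM summaries, 0.3 for the protein summaries — typical medians for noisy
PTM data) at FDR 5% and 80% power:

```{r power}
sample_size(q = 0.05, beta = 0.2, delta_adj = 0.75,
            var_ptm = 0.45, var_protein = 0.3)
solve_power(0.75, 0.45, 0.3, j_ptm = 10)
```

## Known limitations

* Peptides carrying several modification sites are kept as separate
  composite targets, never deconvolved into per-site contributions.
* Site occupancy (stoichiometry) is out of scope; the adjusted fold change
  is a ratio of abundances, not an occupancy difference.
* No between-run or TMT reference-channel normalization is applied before
  modeling; inputs are assumed normalized upstream, and the TMT path is a
  pass-through in this respect.
* The adjustment assumes the PTM and protein inferences are independent,
  which holds when they come from separate acquisitions; when both are
  derived from one run the pooled SE is an approximation.
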