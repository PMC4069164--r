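---
title: "Methods: marker-constrained deconvolution and prognostic analysis"
author: "bloodDeconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-constrained deconvolution and prognostic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloodDeconv)
```

## The problem

Flow cytometry cannot reliably measure immune-cell composition in
long-term banked blood specimens, but bulk gene expression can still be
assayed. `bloodDeconv` estimates the proportions of immune cell types
(e.g. B, T, NK, dendritic cells and monocytes in PBMC) from a bulk
expression matrix, then asks whether those proportions predict overall
survival; a companion arm stratifies tissue cohorts by the expression of
an MHC/HLA (antigen presentation) gene panel.

## The mixture model and the ssKL fit

The expression of gene $i$ in sample $j$ is modeled as a proportion-
weighted sum over the $r$ constituent cell types,
$x_{ij} = \sum_t w_{it} h_{tj} + \varepsilon_{ij}$, i.e. $X \approx WH$
with $W \ge 0$ ($n \times r$) and $H \ge 0$ ($r \times p$). Both factors
are estimated by multiplicative Lee–Seung updates for the generalized
Kullback–Leibler divergence
$D(X\|WH) = \sum_{ij}\left[x_{ij}\log\frac{x_{ij}}{(WH)_{ij}} -
x_{ij} + (WH)_{ij}\right]$, which are monotone: each sweep does not
increase $D$. Semi-supervision enters through a **marker mask**: each
marker gene's row of $W$ is constrained to its owning cell type (all
other entries held at exactly zero, re-imposed after every update).
Genes claimed by two marker sets are ambiguous and dropped. By default
(`mode = "markers_only"`) the fit is restricted to the matched marker
rows, which makes the model identifiable and fast; `mode = "all_genes"`
retains non-marker rows with unconstrained basis entries.

Numerical choices:

* allowed entries are floored at $10^{-12}$ so the multiplicative
  updates never extinguish their own support;
* convergence is declared when the relative divergence change drops
  below `tol` (default $10^{-6}$), with a cap of `maxIter = 2000`
  sweeps;
* `nRestarts = 10` seeded random initializations (entries uniform on
  $(10^{-3}, 1)$, jointly rescaled so $\overline{W_0H_0} \approx
  \bar X$) are run and the lowest-divergence fit kept; restart $k$ uses
  `seed + k - 1`, so a single base seed reproduces the fit bit for bit.

### Identifiability of proportions (the gauge)

Any NMF solution admits the rescaling $(WD)(D^{-1}H)$ with diagonal
$D > 0$ at unchanged divergence, so the *scale* of each cell type is not
determined by the data: mixing rows are only proportions under a
convention for the per-type scale of $W$ — biologically, per-cell mRNA
content. `bloodDeconv` makes that convention explicit at both ends:

* `generateSignatures()` rescales every cell type's marker profile to a
  common mean marker intensity, so that the simulated mixing weights
  *are* the cell proportions;
* `deconvolve()` fixes the gauge after convergence by rescaling each
  basis column to unit mean over that type's marker genes (a
  KL-invariant transformation), and only then rescales each column of
  $H$ to sum to one.

Without such a convention "true proportions" would not even be a
well-defined target of the estimator. Real marker panels are curated to
comparable specificity but not to calibrated per-cell intensity, so on
real data the estimates should be read as *relative* composition — the
reason the literature validates deconvolution by correlation and mean
absolute difference rather than absolute agreement.

## Synthetic data: what it emulates, and what not

The generator module produces every input of the pipeline with known
ground truth:

* **Signatures** — log-normal intensities (positive, right-skewed, like
  microarray scale data), default 20 exclusive markers per type at a
  mean intensity of 500 and 100 background genes at mean 100, within-
  type log-sd 0.5.
* **Mixtures** — `X = basis %*% H + noise`, $H$ columns
  Dirichlet($\alpha$) with flat $\alpha = 1$ by default; additive
  Gaussian noise (default sd 25, i.e. ~5% of the mean marker intensity)
  truncated at zero. Additive truncated noise was chosen over
  multiplicative noise as the simpler model adequate for recovery
  testing.
* **Survival** — exponential event times with hazard
  $\lambda_0 e^{\beta\,\text{flag}}$ (default baseline 0.02/month,
  median survival near 3 years), independent exponential censoring
  (0.01/month) truncated at 120 months of administrative follow-up.
  The censoring mechanism is a modeling choice of this package; the
  source cohorts do not document theirs.
* **MHC panels** — 18 genes by default; per-gene baselines
  $N(10, 1)$, a planted Low cluster shifted down by `separation`
  (default 3) and unit-sd noise.

Not emulated: probe-level bead-array artifacts, batch effects, quantile
normalization, gene–gene correlation within a cell type, and marker
genes that are merely *predominant* rather than exclusive. Passing the
synthetic recovery tests therefore demonstrates algorithmic
correctness — the estimator recovers the truth under its own model —
not field performance on real cohorts, where marker impurity and
mRNA-content differences dominate the error budget.

## Survival statistics

Groups are formed by the **median split** rule: Low strictly below the
sample median, High at or above it (even $n$: mean of the two central
order statistics). Kaplan–Meier curves, log-rank tests and Cox models
are computed by the `survival` package behind this package's interface;
brute-force re-implementations in the test suite serve as independent
oracles. Conventions:

* Cox ties: Efron approximation; CIs: Wald on the log-HR scale,
  $\exp(\hat\beta \pm 1.96\,\text{se})$.
* Univariate screening applies the raw $p < .05$ rule per factor with
  **no multiple-testing adjustment** — deliberately mirroring common
  practice in clinical profiling studies; treat marginal selections
  accordingly.
* Categorical covariates are dummy-coded against their first level;
  levels meaning "unknown" (e.g. "Not sure") are excluded from the
  affected test but the samples stay in the cohort.
* Complete separation or non-convergence in the Cox fit is flagged
  (`converged = FALSE`), never silently reported.

## Two-means stratification

Lloyd's algorithm with $k = 2$ and Euclidean distance
$d(u,v) = \sqrt{\sum_g (e_{gu} - e_{gv})^2}$ over the panel genes, 25
seeded restarts, best within-cluster sum of squares kept. An emptied
cluster is re-seeded at the sample farthest from the surviving
centroid. Panels are clustered on raw intensities — no per-gene
standardization — because the distance is defined on expression
intensities directly; this is configurable upstream by transforming the
matrix. The cluster with the smaller centroid mean is labeled Low; an
exact tie (possible only on degenerate data) is broken toward the
smaller cluster with a message. `stratifyAndTest()` composes
clustering, log-rank, covariate-adjusted Cox and the label × relapse
chi-square (samples with unknown relapse excluded from that test only).

## Pipeline drivers and reproducibility

`runPbmcArm()` and `runTissueArm()` execute the two arms from a YAML
config: deconvolution → per-type median split → log-rank screen →
multivariate Cox (blood), and panel clustering → log-rank → adjusted
Cox → relapse chi-square (tissue). One top-level seed drives every
stochastic stage; outputs are TSV tables stamped with the seed and an
MD5 hash of the config, plus a JSON report. Two runs with the same
config and seed are byte-identical.

Whether the blood arm's T-cell and T-helper groupings belong in one
joint multivariate model or two separate ones is genuinely ambiguous in
practice; the driver includes every screened-in grouping jointly, which
is the stricter adjustment, and single-model runs can be obtained by
restricting the marker scheme.

## Problem sizes and validation scale

The shipped tests validate at desk scale, chosen so the full suite runs
in seconds-to-minutes on one CPU: recovery on 10 replicate datasets of
24 mixture samples (4 cell types, 20 markers each), divergence
monotonicity on 100 small random instances, survival oracles on
≤ 8-record cohorts where exhaustive computation is feasible, log-rank
calibration on 1000 null cohorts of 150 samples, Cox consistency at
n = 2000, and planted-panel recovery on 100-sample 18-gene panels.
Cohort-level results from archived clinical series require the original
repositories and are intentionally outside the test surface.

## Known limitations

* Exclusive (single-type) markers are assumed; impure markers bias
  proportions toward the contaminating types.
* Proportions are relative to the modeled cell types only — a type
  absent from the marker scheme is silently absorbed by the others.
* The Cox and log-rank machinery assumes proportional hazards and
  right-censoring non-informative of group; no diagnostics are run.
* Two-means stratification imposes exactly two groups regardless of the
  true structure of the panel.
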