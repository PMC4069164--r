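# bloodDeconv

Retrospective survival studies often rely on banked blood specimens with
long-term follow-up, where flow cytometry is no longer reliable because
cell-surface proteins degrade under cryopreservation. Gene expression,
by contrast, survives banking well — so the composition of immune cells
in a stored specimen can instead be *deconvolved* from its bulk
expression profile. `bloodDeconv` implements that workflow end to end
for R users in cancer immunology and biomarker research:

1. **Deconvolution.** A bulk profile is modeled as a linear mixture of
   cell-type expression profiles,

   `x_ij = Σ_t w_it · h_tj + ε_ij`,   i.e.   `X ≈ W H`,

   with `W` (genes × cell types) the per-type expression signatures and
   `H` (cell types × samples) the mixing proportions. Both factors are
   estimated by semi-supervised non-negative matrix factorization
   minimizing the generalized Kullback–Leibler divergence
   `D(X‖WH) = Σ_ij [x_ij log(x_ij/(WH)_ij) − x_ij + (WH)_ij]`, with
   marker genes (IRIS- or HaemAtlas-style GMT sets) constraining each
   marker row of `W` to its owning cell type. Columns of `H` are
   rescaled to the simplex: the cell types jointly account for 100% of
   the sample.
2. **Prognosis.** Each cell-type proportion is median-split into Low
   (< median) and High (≥ median) groups, compared by Kaplan–Meier /
   log-rank analysis, screened together with clinical factors at
   p < .05, and carried into a multivariate Cox proportional-hazards
   model (Efron ties, Wald CIs).
3. **Tissue stratification.** Samples of a tissue cohort are split into
   MHC-Low / MHC-High antigen-presentation groups by two-means
   clustering (Euclidean distance) on an MHC gene panel, then tested by
   log-rank, adjusted Cox, and a chi-square test of relapse enrichment.

A synthetic-data module generates every input with known ground truth —
exclusive-marker signatures, Dirichlet mixtures, proportional-hazards
survival cohorts, planted two-cluster panels — so the whole pipeline is
validated without any external download.

## Worked example

```r
library(bloodDeconv)

# simulate a 5-type PBMC-like cohort with known proportions
sig <- generateSignatures(c("B", "T", "NK", "DC", "Mono"), seed = 1)
mix <- generateMixtures(sig, nSamples = 60, noiseSd = 25, seed = 2)

fit <- deconvolve(exprs(mix), markerSets(mix), nRestarts = 10, seed = 42)
fit
#> DeconvolutionResult: 100 genes, 5 cell types, 60 samples
#>   final KL divergence 31828.1 after 2 iterations (10 restarts)

evaluateRecovery(trueProportions(mix), proportions(fit))
#> $mad
#> [1] 0.007795319
#> $pearson_r
#> [1] 0.9986166
```

The estimated proportions differ from the simulated truth by a mean
absolute difference of about 0.007 (on the 0–1 proportion scale) with a
Pearson correlation above 0.99. Survival follow-up of a median split:

```r
tcell <- proportions(fit)["T", ]
grp <- medianSplit(tcell)
coh <- generateSurvival(as.integer(tcell < grp$median), beta = log(2.2),
                        seed = 3, sampleId = names(tcell))
logrankTest(survTime(coh), survEvent(coh), grp$labels)
#> $chi2
#> [1] 10.88965
#> $df
#> [1] 1
#> $p
#> [1] 0.0009670314

coxFit(coh, "group")$table
#>       term     coef        se hazard_ratio   ci_low ci_high           p
#> 1 groupLow 1.018968 0.3199049     2.770335 1.479871  5.1861 0.001446423
```

The Low T-cell group carries a hazard ratio of ~2.8 with a significant
log-rank difference — the planted effect is recovered. Both end-to-end
arms can also be driven from a YAML config via `runPbmcArm()` /
`runTissueArm()`, which write stamped TSV tables and a JSON report.

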