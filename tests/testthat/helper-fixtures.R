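# Build a complete on-disk PBMC-arm fixture: expression TSV, GMT marker
# file and clinical TSV, with survival optionally driven by the true
# T-cell proportion (Low T => hazard ratio exp(beta)).
makePbmcFixture <- function(dir, nSamples = 60, beta = log(3), seed = 1,
                            types = c("B", "T", "NK", "DC", "Mono")) {
    sig <- generateSignatures(types, seed = seed)
    mix <- generateMixtures(sig, nSamples, noiseSd = 25, seed = seed + 1)
    tProp <- trueProportions(mix)["T", ]
    lowFlag <- as.integer(tProp < median(tProp))
    coh <- generateSurvival(lowFlag, beta = beta, seed = seed + 2,
                            sampleId = colnames(exprs(mix)))
    covar <- covariates(coh)
    covar$group <- NULL
    set.seed(seed + 3)
    covar$stage <- factor(sample(c("I", "II-III"), nSamples,
                                 replace = TRUE))
    covar$gender <- factor(sample(c("male", "female"), nSamples,
                                  replace = TRUE))
    coh <- SurvivalCohort(sampleIds(coh), survTime(coh), survEvent(coh),
                          covar)
    paths <- list(expression = file.path(dir, "expr.tsv"),
                  markers = file.path(dir, "markers.gmt"),
                  clinical = file.path(dir, "clinical.tsv"))
    writeExpression(exprs(mix), paths$expression)
    writeGMT(markerSets(mix), paths$markers)
    writeClinical(coh, paths$clinical)
    c(paths, list(mixture = mix, cohort = coh, lowFlag = lowFlag))
}

makePbmcConfig <- function(fix, outDir, seed = 5,
                           screen = c("stage", "gender"), restarts = 4) {
    list(expression = fix$expression, markers = fix$markers,
         clinical = fix$clinical, output_dir = outDir,
         seed = as.integer(seed),
         deconvolution = list(mode = "markers_only", restarts = restarts,
                              max_iter = 2000L, tol = 1e-6),
         survival = list(screen = screen, alpha = 0.05, relapse = NULL),
         stratification = list(restarts = 25L))
}
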