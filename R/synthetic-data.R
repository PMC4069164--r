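#' @include methods-accessors.R
NULL

## Draw log-normal intensities. Microarray-style intensities are positive
## and right-skewed, which the log-normal gives by construction.
.rlnormMat <- function(n, m, meanlog, sdlog) {
    matrix(stats::rlnorm(n * m, meanlog = meanlog, sdlog = sdlog), n, m)
}

#' Generate cell-type expression signatures with exclusive marker genes
#'
#' Builds a genes x cell-types basis matrix in which each cell type owns a
#' block of marker genes expressed in that type only (exactly zero in every
#' other column), plus background genes expressed in all types. Marker and
#' background intensities are log-normal on the intensity scale. Each
#' type's marker profile is rescaled to a common mean marker intensity:
#' mixing weights of such signatures are directly interpretable as cell
#' proportions, which is the identifiability convention the deconvolution
#' assumes (per-type scale is otherwise confounded with per-cell mRNA
#' content).
#'
#' @param cellTypes character vector of cell-type names (>= 2), e.g. the
#'   five PBMC types B, T, NK, DC, monocytes.
#' @param markersPerType number of exclusive marker genes per type (>= 1).
#' @param backgroundGenes number of genes expressed in all types (>= 0).
#' @param markerMean,backgroundMean log-scale mean intensities.
#' @param withinTypeSd log-scale standard deviation of intensities.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return list with `basis` (genes x types matrix) and `markerSets`
#'   (a [MarkerSetCollection-class]).
#' @examples
#' sig <- generateSignatures(c("B", "T", "NK"), markersPerType = 5,
#'                           backgroundGenes = 10, seed = 1)
#' dim(sig$basis)
#' @export
generateSignatures <- function(cellTypes, markersPerType = 20L,
                               backgroundGenes = 100L,
                               markerMean = log(500),
                               backgroundMean = log(100),
                               withinTypeSd = 0.5, seed = 1L) {
    if (length(cellTypes) < 2L || anyDuplicated(cellTypes))
        stop("need >= 2 distinct cell-type names")
    if (markersPerType < 1L) stop("markersPerType must be >= 1")
    if (backgroundGenes < 0L) stop("backgroundGenes must be >= 0")
    stopifnot(is.finite(markerMean), is.finite(backgroundMean),
              is.finite(withinTypeSd), withinTypeSd >= 0)
    r <- length(cellTypes)
    set.seed(as.integer(seed))
    markerTarget <- exp(markerMean + withinTypeSd^2 / 2)
    sets <- vector("list", r); names(sets) <- cellTypes
    blocks <- vector("list", r)
    for (t in seq_len(r)) {
        genes <- sprintf("%s_marker_%02d", cellTypes[t],
                         seq_len(markersPerType))
        v <- stats::rlnorm(markersPerType, markerMean, withinTypeSd)
        v <- v * markerTarget / mean(v)   # common per-type marker scale
        blk <- matrix(0, markersPerType, r,
                      dimnames = list(genes, cellTypes))
        blk[, t] <- v
        blocks[[t]] <- blk
        sets[[t]] <- genes
    }
    basis <- do.call(rbind, blocks)
    if (backgroundGenes > 0L) {
        bg <- .rlnormMat(backgroundGenes, r, backgroundMean, withinTypeSd)
        dimnames(bg) <- list(sprintf("bg_%04d", seq_len(backgroundGenes)),
                             cellTypes)
        basis <- rbind(basis, bg)
    }
    list(basis = basis, markerSets = MarkerSetCollection(sets))
}

#' Draw Dirichlet-distributed proportion columns
#'
#' @param n number of columns (samples)
#' @param alpha positive concentration parameters, one per component
#' @return length(alpha) x n matrix with simplex columns
#' @keywords internal
.rdirichlet <- function(n, alpha) {
    r <- length(alpha)
    g <- matrix(stats::rgamma(r * n, shape = alpha), r, n)
    sweep(g, 2L, colSums(g), "/")
}

#' Generate synthetic bulk mixtures with known proportions
#'
#' Mixes cell-type signatures with Dirichlet-distributed proportions:
#' expression = basis %*% H + Gaussian noise, truncated at zero (the bulk
#' intensity of a gene is the proportion-weighted sum of its intensities
#' in the constituent cell types).
#'
#' @param signatures output of [generateSignatures()], or a list with
#'   elements `basis` and `markerSets`.
#' @param nSamples number of mixture samples.
#' @param dirichletAlpha positive Dirichlet concentrations, one per cell
#'   type (default flat: alpha = 1 for every type).
#' @param noiseSd standard deviation of additive Gaussian noise on the
#'   intensity scale (>= 0); noise is truncated so expression stays
#'   non-negative.
#' @param seed integer seed.
#' @return a [MixtureDataset-class]
#' @examples
#' sig <- generateSignatures(c("B", "T", "NK"), 5, 10, seed = 1)
#' mix <- generateMixtures(sig, nSamples = 8, noiseSd = 0, seed = 2)
#' colSums(trueProportions(mix))
#' @export
generateMixtures <- function(signatures, nSamples,
                             dirichletAlpha = NULL, noiseSd = 25,
                             seed = 1L) {
    basis <- signatures$basis
    msc <- signatures$markerSets
    r <- ncol(basis)
    if (is.null(dirichletAlpha)) dirichletAlpha <- rep(1, r)
    if (length(dirichletAlpha) != r || any(dirichletAlpha <= 0))
        stop("dirichletAlpha must give one positive value per cell type")
    if (noiseSd < 0) stop("noiseSd must be non-negative")
    if (nSamples < 1L) stop("nSamples must be >= 1")
    set.seed(as.integer(seed))
    H <- .rdirichlet(nSamples, dirichletAlpha)
    dimnames(H) <- list(colnames(basis),
                        sprintf("sample_%03d", seq_len(nSamples)))
    X <- basis %*% H
    if (noiseSd > 0)
        X <- X + matrix(stats::rnorm(length(X), 0, noiseSd),
                        nrow(X), ncol(X))
    X <- pmax(X, 0)
    dimnames(X) <- list(rownames(basis), colnames(H))
    new("MixtureDataset", expression = X, trueBasis = basis,
        trueProportions = H, markerSets = msc,
        noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Simulate a right-censored survival cohort under proportional hazards
#'
#' Event times are exponential with hazard `baselineRate * exp(beta *
#' flag)`, where `flag` marks the at-risk (e.g. marker-Low) group;
#' censoring is an independent exponential truncated at an administrative
#' follow-up cutoff. Observed time is the minimum of event and censoring
#' times.
#'
#' @param lowFlags 0/1 vector, 1 for samples in the elevated-hazard group.
#' @param beta log hazard ratio of flagged vs unflagged samples.
#' @param baselineRate baseline event rate per month (> 0).
#' @param censorRate censoring rate per month (> 0).
#' @param maxFollowup administrative censoring time in months (> 0).
#' @param seed integer seed.
#' @param sampleId optional sample identifiers.
#' @return a [SurvivalCohort-class] whose covariates carry the grouping as
#'   factor `group` with levels c("High","Low") ("Low" = flagged).
#' @examples
#' coh <- generateSurvival(rep(0:1, each = 20), beta = log(2), seed = 7)
#' table(covariates(coh)$group, survEvent(coh))
#' @export
generateSurvival <- function(lowFlags, beta = 0, baselineRate = 0.02,
                             censorRate = 0.01, maxFollowup = 120,
                             seed = 1L, sampleId = NULL) {
    if (!all(lowFlags %in% c(0, 1))) stop("lowFlags must be binary")
    if (baselineRate <= 0 || censorRate <= 0)
        stop("rates must be positive")
    if (maxFollowup <= 0) stop("maxFollowup must be positive")
    n <- length(lowFlags)
    if (is.null(sampleId)) sampleId <- sprintf("sample_%03d", seq_len(n))
    set.seed(as.integer(seed))
    hazard <- baselineRate * exp(beta * lowFlags)
    tEvent <- stats::rexp(n, rate = hazard)
    tCens <- pmin(stats::rexp(n, rate = censorRate), maxFollowup)
    obs <- pmin(tEvent, tCens)
    ev <- as.integer(tEvent <= tCens)
    covar <- data.frame(
        group = factor(ifelse(lowFlags == 1, "Low", "High"),
                       levels = c("High", "Low")),
        row.names = sampleId)
    SurvivalCohort(sampleId, obs, ev, covar)
}

#' Generate an MHC-like expression panel with two planted clusters
#'
#' Emulates a small panel of antigen-presentation genes whose joint
#' expression separates samples into a Low and a High group: every gene
#' gets a baseline mean, samples of the planted Low cluster are shifted
#' down by `separation`, and i.i.d. Gaussian noise is added (truncated at
#' zero so intensities stay non-negative).
#'
#' @param nSamples number of samples.
#' @param nGenes panel size (>= 1); the study-scale default is an 18-gene
#'   MHC panel.
#' @param clusterFraction fraction of samples in the Low cluster,
#'   strictly between 0 and 1.
#' @param separation mean down-shift of the Low cluster (>= 0), in the
#'   same units as `noiseSd`.
#' @param noiseSd per-entry Gaussian noise sd.
#' @param baseMean per-gene baseline means are N(baseMean, 1).
#' @param seed integer seed.
#' @return list with `expression` (genes x samples matrix) and
#'   `trueLabels` (factor, levels c("Low","High")).
#' @examples
#' pan <- generateMhcPanel(50, separation = 5, seed = 3)
#' table(pan$trueLabels)
#' @export
generateMhcPanel <- function(nSamples, nGenes = 18L, clusterFraction = 0.4,
                             separation = 3, noiseSd = 1, baseMean = 10,
                             seed = 1L) {
    if (nGenes < 1L) stop("nGenes must be >= 1")
    if (clusterFraction <= 0 || clusterFraction >= 1)
        stop("clusterFraction must lie strictly between 0 and 1")
    if (separation < 0) stop("separation must be >= 0")
    set.seed(as.integer(seed))
    nLow <- max(1L, min(nSamples - 1L, round(clusterFraction * nSamples)))
    lab <- factor(c(rep("Low", nLow), rep("High", nSamples - nLow)),
                  levels = c("Low", "High"))
    lab <- lab[sample.int(nSamples)]
    mu <- stats::rnorm(nGenes, baseMean, 1)
    X <- matrix(mu, nGenes, nSamples)
    X[, lab == "Low"] <- X[, lab == "Low"] - separation
    X <- X + matrix(stats::rnorm(nGenes * nSamples, 0, noiseSd),
                    nGenes, nSamples)
    X <- pmax(X, 0)
    dimnames(X) <- list(sprintf("MHC_%02d", seq_len(nGenes)),
                        sprintf("sample_%03d", seq_len(nSamples)))
    names(lab) <- colnames(X)
    list(expression = X, trueLabels = lab)
}
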