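#' @import methods
NULL

.checkExpressionMatrix <- function(x, what = "expression matrix",
                                   allowNegative = FALSE) {
    if (!is.matrix(x) || !is.numeric(x))
        stop(what, " must be a numeric matrix (genes x samples)")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop(what, " must carry gene rownames and sample colnames")
    if (anyDuplicated(rownames(x)))
        stop(what, " has duplicated gene identifiers")
    if (anyDuplicated(colnames(x)))
        stop(what, " has duplicated sample identifiers")
    if (any(!is.finite(x)))
        stop(what, " contains non-finite values")
    if (!allowNegative && any(x < 0))
        stop(what, " contains negative values; floor at zero first")
    invisible(TRUE)
}

#' Collection of per-cell-type marker gene sets
#'
#' Ordered collection mapping cell-type names to marker gene identifiers,
#' as read from a GMT file or produced by the signature generator. Marker
#' schemes of this shape (IRIS- or HaemAtlas-style, one gene list per
#' immune cell type) anchor the semi-supervised deconvolution: a marker
#' gene is assumed expressed in its owning cell type only.
#'
#' @slot sets named list of character vectors, one per cell type, in a
#'   fixed (user-supplied) order; each non-empty, no within-set duplicates.
#' @slot descriptions named character vector of free-text set descriptions.
#'
#' @seealso [readGMT()], [generateSignatures()], [buildMarkerMask()]
#' @export
setClass("MarkerSetCollection",
    representation(sets = "list", descriptions = "character"))

setValidity("MarkerSetCollection", function(object) {
    s <- object@sets
    if (length(s) < 2L)
        return("need at least 2 cell types")
    if (is.null(names(s)) || any(!nzchar(names(s))) || anyDuplicated(names(s)))
        return("cell-type names must be unique and non-empty")
    for (nm in names(s)) {
        g <- s[[nm]]
        if (!is.character(g) || length(g) == 0L)
            return(sprintf("marker set '%s' is empty", nm))
        if (anyDuplicated(g))
            return(sprintf("marker set '%s' has duplicated genes", nm))
    }
    TRUE
})

#' Synthetic mixture dataset with known ground truth
#'
#' Holds a simulated bulk expression matrix together with the true
#' cell-type proportions used to mix it, so that deconvolution accuracy
#' can be measured exactly.
#'
#' @slot expression non-negative genes x samples matrix
#'   (signatures %*% proportions plus truncated Gaussian noise).
#' @slot trueBasis genes x cell-types signature matrix used for mixing.
#' @slot trueProportions cell-types x samples matrix; columns on the
#'   probability simplex.
#' @slot markerSets the [MarkerSetCollection-class] describing which rows
#'   are type-exclusive markers.
#' @slot noiseSd standard deviation of the additive noise.
#' @slot seed integer seed the dataset was generated under.
#'
#' @seealso [generateMixtures()]
#' @export
setClass("MixtureDataset",
    representation(expression = "matrix", trueBasis = "matrix",
                   trueProportions = "matrix",
                   markerSets = "MarkerSetCollection",
                   noiseSd = "numeric", seed = "integer"))

setValidity("MixtureDataset", function(object) {
    X <- object@expression
    H <- object@trueProportions
    if (any(X < 0)) return("expression entries must be non-negative")
    if (ncol(X) != ncol(H)) return("sample dimensions disagree")
    if (nrow(H) != length(object@markerSets@sets))
        return("proportion rows must match the number of cell types")
    cs <- colSums(H)
    if (any(H < 0) || any(abs(cs - 1) > 1e-9))
        return("true proportion columns must lie on the simplex")
    TRUE
})

#' Result of marker-constrained KL-NMF deconvolution
#'
#' The factorization X ~ W H returned by [deconvolve()]: W (basis) holds
#' the per-cell-type expression profiles, H (mixing) the per-sample
#' loadings, and `proportions` the columns of H rescaled to sum to one --
#' the estimated cell-type fractions of each sample.
#'
#' @slot basis genes x types matrix W; entries disallowed by the marker
#'   mask are exactly zero.
#' @slot rawMixing types x samples matrix H as fitted (before simplex
#'   rescaling).
#' @slot proportions types x samples matrix; columns non-negative,
#'   summing to 1.
#' @slot mask logical genes x types matrix of allowed basis support.
#' @slot divergenceTrace generalized KL divergence after each iteration of
#'   the best restart; non-increasing.
#' @slot nIter iterations run by the best restart.
#' @slot seed base seed of the fit.
#' @slot restartsTried number of random restarts evaluated.
#'
#' @seealso [deconvolve()], [proportions()], [basisMatrix()]
#' @export
setClass("DeconvolutionResult",
    representation(basis = "matrix", rawMixing = "matrix",
                   proportions = "matrix", mask = "matrix",
                   divergenceTrace = "numeric", nIter = "integer",
                   seed = "integer", restartsTried = "integer"))

setValidity("DeconvolutionResult", function(object) {
    W <- object@basis; H <- object@proportions
    if (any(W < 0) || any(object@rawMixing < 0) || any(H < 0))
        return("factors must be non-negative")
    if (any(W[!object@mask] != 0))
        return("masked basis entries must be exactly zero")
    cs <- colSums(H)
    if (any(abs(cs - 1) > 1e-9))
        return("proportion columns must sum to 1")
    d <- object@divergenceTrace
    ## round-off near an exact fit scales with the initial divergence,
    ## not the (possibly ~0) current one
    if (length(d) > 1L && any(diff(d) > 1e-8 * (d[1L] + 1)))
        return("divergence trace must be non-increasing")
    TRUE
})

#' Right-censored survival cohort
#'
#' Per-sample overall survival (time from resection to death or last
#' contact), an event indicator, and categorical clinical covariates.
#'
#' @slot sampleId character sample identifiers (unique).
#' @slot time non-negative follow-up times (months).
#' @slot event integer 0/1 (1 = death observed, 0 = censored).
#' @slot covariates data.frame of per-sample covariates (factors or
#'   character), rownames = sampleId; may have zero columns.
#'
#' @seealso [readClinical()], [generateSurvival()]
#' @export
setClass("SurvivalCohort",
    representation(sampleId = "character", time = "numeric",
                   event = "integer", covariates = "data.frame"))

setValidity("SurvivalCohort", function(object) {
    n <- length(object@sampleId)
    if (anyDuplicated(object@sampleId)) return("duplicate sample IDs")
    if (length(object@time) != n || length(object@event) != n)
        return("time/event length must match sample IDs")
    if (any(!is.finite(object@time)) || any(object@time < 0))
        return("survival times must be finite and non-negative")
    if (!all(object@event %in% c(0L, 1L)))
        return("event indicator must be 0/1")
    if (nrow(object@covariates) != n)
        return("covariate rows must match sample IDs")
    TRUE
})

#' Two-group stratification of samples on a gene panel
#'
#' Result of two-means clustering of samples on an expression panel
#' (e.g. MHC genes), labeled Low/High by centroid mean: the Low group is
#' the cluster with the smaller average expression.
#'
#' @slot labels factor of per-sample labels, levels c("Low","High"),
#'   named by sample.
#' @slot centroids 2 x m matrix (rows "Low","High") of cluster centroids.
#' @slot withinss total within-cluster sum of squares of the kept run.
#' @slot objectiveTrace within-cluster sum of squares after each Lloyd
#'   iteration of the kept run; non-increasing.
#' @slot nIter Lloyd iterations of the kept run.
#' @slot seed base seed.
#'
#' @seealso [kmeansTwo()], [stratifyAndTest()]
#' @export
setClass("StratificationResult",
    representation(labels = "factor", centroids = "matrix",
                   withinss = "numeric", objectiveTrace = "numeric",
                   nIter = "integer", seed = "integer"))

setValidity("StratificationResult", function(object) {
    if (!identical(levels(object@labels), c("Low", "High")))
        return("labels must have levels Low, High")
    if (nrow(object@centroids) != 2L)
        return("exactly two centroids required")
    tab <- table(object@labels)
    if (any(tab == 0L)) return("both clusters must be non-empty")
    d <- object@objectiveTrace
    if (length(d) > 1L && any(diff(d) > 1e-8 * pmax(d[-length(d)], 1)))
        return("objective trace must be non-increasing")
    TRUE
})
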