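#' @include AllGenerics.R
NULL

## ---- MarkerSetCollection ----

#' Construct a MarkerSetCollection
#'
#' @param sets named list of character vectors of marker gene IDs, one per
#'   cell type, in the desired order.
#' @param descriptions optional character vector of set descriptions.
#' @return a [MarkerSetCollection-class]
#' @examples
#' msc <- MarkerSetCollection(list(B = c("CD19", "MS4A1"), T = c("CD3D")))
#' cellTypes(msc)
#' @export
MarkerSetCollection <- function(sets, descriptions = NULL) {
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    new("MarkerSetCollection", sets = sets, descriptions = descriptions)
}

#' @rdname MarkerSetCollection-class
#' @export
setMethod("cellTypes", "MarkerSetCollection", function(x) names(x@sets))

#' @rdname MarkerSetCollection-class
#' @export
setMethod("markerGenes", "MarkerSetCollection", function(x, type = NULL) {
    if (is.null(type)) return(x@sets)
    if (!type %in% names(x@sets))
        stop("unknown cell type: ", type)
    x@sets[[type]]
})

#' @rdname MarkerSetCollection-class
#' @export
setMethod("length", "MarkerSetCollection", function(x) length(x@sets))

setMethod("show", "MarkerSetCollection", function(object) {
    cat(sprintf("MarkerSetCollection with %d cell types\n",
                length(object@sets)))
    for (nm in names(object@sets))
        cat(sprintf("  %-12s %d markers\n", nm, length(object@sets[[nm]])))
})

## ---- MixtureDataset ----

#' @rdname MixtureDataset-class
#' @export
setMethod("exprs", "MixtureDataset", function(x) x@expression)

#' @rdname MixtureDataset-class
#' @export
setMethod("trueProportions", "MixtureDataset", function(x) x@trueProportions)

#' @rdname MixtureDataset-class
#' @export
setMethod("markerSets", "MixtureDataset", function(x) x@markerSets)

setMethod("show", "MixtureDataset", function(object) {
    cat(sprintf("MixtureDataset: %d genes x %d samples, %d cell types\n",
                nrow(object@expression), ncol(object@expression),
                nrow(object@trueProportions)))
    cat(sprintf("  noise sd %.3g, seed %d\n", object@noiseSd, object@seed))
})

## ---- DeconvolutionResult ----

#' @rdname DeconvolutionResult-class
#' @export
setMethod("basisMatrix", "DeconvolutionResult", function(x) x@basis)

#' @rdname DeconvolutionResult-class
#' @export
setMethod("proportions", "DeconvolutionResult", function(x) x@proportions)

#' @rdname DeconvolutionResult-class
#' @export
setMethod("divergenceTrace", "DeconvolutionResult",
          function(x) x@divergenceTrace)

setMethod("show", "DeconvolutionResult", function(object) {
    d <- object@divergenceTrace
    cat(sprintf("DeconvolutionResult: %d genes, %d cell types, %d samples\n",
                nrow(object@basis), ncol(object@basis),
                ncol(object@proportions)))
    cat(sprintf("  final KL divergence %.6g after %d iterations (%d restarts)\n",
                d[length(d)], object@nIter, object@restartsTried))
})

## ---- SurvivalCohort ----

#' Construct a SurvivalCohort
#'
#' @param sampleId character vector of unique sample identifiers.
#' @param time non-negative overall-survival times (months).
#' @param event 0/1 event indicator (1 = death observed).
#' @param covariates data.frame of per-sample categorical covariates.
#' @return a [SurvivalCohort-class]
#' @export
SurvivalCohort <- function(sampleId, time, event,
                           covariates = data.frame()) {
    sampleId <- as.character(sampleId)
    if (nrow(covariates) == 0L && length(sampleId) > 0L)
        covariates <- data.frame(row.names = sampleId)
    rownames(covariates) <- sampleId
    new("SurvivalCohort", sampleId = sampleId, time = as.numeric(time),
        event = as.integer(event), covariates = covariates)
}

#' @rdname SurvivalCohort-class
#' @export
setMethod("sampleIds", "SurvivalCohort", function(x) x@sampleId)

#' @rdname SurvivalCohort-class
#' @export
setMethod("survTime", "SurvivalCohort", function(x) x@time)

#' @rdname SurvivalCohort-class
#' @export
setMethod("survEvent", "SurvivalCohort", function(x) x@event)

#' @rdname SurvivalCohort-class
#' @export
setMethod("covariates", "SurvivalCohort", function(x) x@covariates)

#' @rdname SurvivalCohort-class
#' @export
setMethod("length", "SurvivalCohort", function(x) length(x@sampleId))

#' Subset a cohort by sample
#'
#' @param x a [SurvivalCohort-class]
#' @param i integer, logical or character (sample ID) index
#' @param j,...,drop ignored
#' @export
setMethod("[", "SurvivalCohort", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@sampleId)
    if (anyNA(i)) stop("unknown sample IDs in cohort subset")
    SurvivalCohort(x@sampleId[i], x@time[i], x@event[i],
                   x@covariates[i, , drop = FALSE])
})

setMethod("show", "SurvivalCohort", function(object) {
    cat(sprintf("SurvivalCohort: %d samples, %d events, %d covariates\n",
                length(object@sampleId), sum(object@event),
                ncol(object@covariates)))
    if (ncol(object@covariates))
        cat("  covariates:", paste(colnames(object@covariates),
                                   collapse = ", "), "\n")
})

## ---- StratificationResult ----

#' @rdname StratificationResult-class
#' @export
setMethod("groupLabels", "StratificationResult", function(x) x@labels)

#' @rdname StratificationResult-class
#' @export
setMethod("centroids", "StratificationResult", function(x) x@centroids)

setMethod("show", "StratificationResult", function(object) {
    tab <- table(object@labels)
    cat(sprintf("StratificationResult: Low n=%d, High n=%d\n",
                tab[["Low"]], tab[["High"]]))
    cat(sprintf("  within-cluster SS %.4g after %d iterations\n",
                object@withinss, object@nIter))
})
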