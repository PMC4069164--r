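#' @include AllClasses.R
NULL

#' @rdname MarkerSetCollection-class
#' @param object,x an object of the documented class
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname MarkerSetCollection-class
#' @param type optional cell-type name
#' @export
setGeneric("markerGenes", function(x, type = NULL) standardGeneric("markerGenes"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("proportions", function(x) standardGeneric("proportions"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("divergenceTrace", function(x) standardGeneric("divergenceTrace"))

#' @rdname MixtureDataset-class
#' @export
setGeneric("exprs", function(x) standardGeneric("exprs"))

#' @rdname MixtureDataset-class
#' @export
setGeneric("trueProportions", function(x) standardGeneric("trueProportions"))

#' @rdname MixtureDataset-class
#' @export
setGeneric("markerSets", function(x) standardGeneric("markerSets"))

#' @rdname SurvivalCohort-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SurvivalCohort-class
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname SurvivalCohort-class
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' @rdname SurvivalCohort-class
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname StratificationResult-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname StratificationResult-class
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
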