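#' @include AllClasses.R
NULL

#' Accessors for screen objects
#'
#' `guideIds()` returns guide identifiers, `geneMap()` the named
#' guide-to-gene vector, and `sampleConditions()` the per-sample condition
#' labels of a [ScreenCounts-class] or [NormalizedCounts-class] object.
#'
#' @param x A `ScreenCounts` or `NormalizedCounts` object.
#' @return `guideIds()`: character vector; `geneMap()`: named character
#'   vector (guide -> gene); `sampleConditions()`: character vector.
#' @name screen-accessors
#' @aliases guideIds geneMap sampleConditions
NULL

#' @rdname screen-accessors
#' @export
setGeneric("guideIds", function(x) standardGeneric("guideIds"))

#' @rdname screen-accessors
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))

#' @rdname screen-accessors
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' Accessors for VariantCohort objects
#'
#' `variantCalls()` returns the per-(sample, variant) call table and
#' `sampleInfo()` the sample table (sample_id, group).
#'
#' @param x A [VariantCohort-class] object.
#' @return A `DataFrame`.
#' @name cohort-accessors
#' @aliases variantCalls sampleInfo
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("variantCalls", function(x) standardGeneric("variantCalls"))

#' @rdname cohort-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Accessors for DispersionEstimate objects
#'
#' @param x A [DispersionEstimate-class] object.
#' @return `phiCommon()`: single numeric; `phiTagwise()`: numeric vector
#'   (length 0 when tagwise estimation was not requested).
#' @name dispersion-accessors
#' @aliases phiCommon phiTagwise
NULL

#' @rdname dispersion-accessors
#' @export
setGeneric("phiCommon", function(x) standardGeneric("phiCommon"))

#' @rdname dispersion-accessors
#' @export
setGeneric("phiTagwise", function(x) standardGeneric("phiTagwise"))
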