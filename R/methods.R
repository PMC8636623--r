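#' @include AllGenerics.R
NULL

.assayMatrix <- function(x) {
    if (is(x, "NormalizedCounts")) assay(x, "normcounts")
    else assay(x, "counts")
}

#' @rdname screen-accessors
setMethod("guideIds", "SummarizedExperiment", function(x) rownames(x))

#' @rdname screen-accessors
setMethod("geneMap", "SummarizedExperiment", function(x) {
    stats::setNames(as.character(rowData(x)$gene), rownames(x))
})

#' @rdname screen-accessors
setMethod("sampleConditions", "SummarizedExperiment", function(x) {
    stats::setNames(as.character(colData(x)$condition), colnames(x))
})

#' @rdname cohort-accessors
setMethod("variantCalls", "VariantCohort", function(x) x@calls)

#' @rdname cohort-accessors
setMethod("sampleInfo", "VariantCohort", function(x) x@samples)

#' @rdname dispersion-accessors
setMethod("phiCommon", "DispersionEstimate", function(x) x@phiCommon)

#' @rdname dispersion-accessors
setMethod("phiTagwise", "DispersionEstimate", function(x) x@phiTagwise)

#' @exportMethod show
setMethod("show", "ScreenCounts", function(object) {
    cat(sprintf("ScreenCounts: %d guides x %d samples (%d genes)\n",
                nrow(object), ncol(object),
                length(unique(rowData(object)$gene))))
    tab <- table(colData(object)$condition)
    cat("conditions:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
})

setMethod("show", "NormalizedCounts", function(object) {
    cat(sprintf("NormalizedCounts: %d guides x %d samples\n",
                nrow(object), ncol(object)))
    cat("normalized reads per sgRNA (pseudo-count floor 1)\n")
})

setMethod("show", "VariantCohort", function(object) {
    s <- sampleInfo(object)
    cat(sprintf("VariantCohort: %d calls, %d variants, %d samples\n",
                nrow(object@calls),
                length(unique(object@calls$variant_id)), nrow(s)))
    tab <- table(factor(s$group, levels = .IMMUNE_GROUPS))
    tab <- tab[tab > 0]
    cat("groups:",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
})

setMethod("show", "DispersionEstimate", function(object) {
    cat(sprintf("DispersionEstimate: common phi = %.4g\n", object@phiCommon))
    if (length(object@phiTagwise))
        cat(sprintf("tagwise: %d guides, shrinkage weight %.3g\n",
                    length(object@phiTagwise), object@shrinkageWeight))
})
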