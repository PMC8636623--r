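#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
NULL

## controlled vocabularies shared across the package
.IMMUNE_GROUPS <- c("in_vitro", "immunodeficient", "immunocompetent",
                    "immunotherapy_aPD1", "immunotherapy_aPDL1")
.ICB_GROUPS <- c("immunotherapy_aPD1", "immunotherapy_aPDL1")
.ANNOTATIONS <- c("missense", "splicing", "frameshift", "deletion", "other")
.CATEGORIES <- c("PD1_dependent", "PD1_independent")

#' Immune-pressure group labels
#'
#' The five group labels a cohort sample may carry: one cultured (in vitro)
#' baseline group, tumors grown in immunodeficient hosts, tumors grown in
#' immunocompetent hosts, and two checkpoint-blockade arms (anti-PD-1 and
#' anti-PD-L1).
#'
#' @return Character vector of the five valid group labels.
#' @export
#' @examples
#' immuneGroups()
immuneGroups <- function() .IMMUNE_GROUPS

#' Functional annotation classes for variants
#'
#' @return Character vector of the valid annotation classes.
#' @export
annotationClasses <- function() .ANNOTATIONS

# ---------------------------------------------------------------------------
# ScreenCounts / NormalizedCounts
# ---------------------------------------------------------------------------

#' ScreenCounts: sgRNA count matrix with guide-to-gene map
#'
#' A \linkS4class{SummarizedExperiment} holding one integer assay
#' \code{"counts"} (guides x samples), a \code{gene} column in
#' \code{rowData} mapping each guide to exactly one gene, and
#' \code{condition}/\code{replicate} columns in \code{colData}.
#'
#' @aliases ScreenCounts-class
#' @exportClass ScreenCounts
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
    msg <- character()
    if (!("counts" %in% assayNames(object)))
        return("assay 'counts' is required")
    m <- assay(object, "counts")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "guide IDs (rownames) must be present and unique")
    if (!("gene" %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain a 'gene' column")
    if (!("condition" %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain a 'condition' column")
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(m != round(m))) msg <- c(msg, "counts must be integers")
    if (ncol(m) > 0L && any(colSums(m) <= 0))
        msg <- c(msg, "every sample must have a positive column total")
    if (length(msg)) msg else TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts Non-negative integer matrix, guides x samples, with unique
#'   rownames (guide IDs) and colnames (sample IDs).
#' @param gene Character vector, one gene symbol per guide.
#' @param condition Character vector, one condition label per sample.
#' @param replicate Optional integer replicate index per sample; defaults to
#'   a running index within each condition.
#' @return A \linkS4class{ScreenCounts} object.
#' @export
#' @examples
#' m <- matrix(rpois(12, 100), nrow = 4,
#'             dimnames = list(paste0("sg", 1:4), paste0("s", 1:3)))
#' sc <- ScreenCounts(m, gene = rep(c("A", "B"), each = 2),
#'                    condition = c("ref", "ref", "sel"))
#' sc
ScreenCounts <- function(counts, gene, condition, replicate = NULL) {
    counts <- as.matrix(counts)
    if (is.double(counts) && all(counts == round(counts)) &&
        max(counts) <= .Machine$integer.max)
        storage.mode(counts) <- "integer"
    if (length(gene) != nrow(counts))
        stop("'gene' must have one entry per guide")
    if (length(condition) != ncol(counts))
        stop("'condition' must have one entry per sample")
    if (is.null(replicate)) {
        replicate <- stats::ave(seq_along(condition),
                                as.character(condition), FUN = seq_along)
    }
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(gene = as.character(gene),
                            row.names = rownames(counts)),
        colData = DataFrame(condition = as.character(condition),
                            replicate = as.integer(replicate),
                            row.names = colnames(counts)))
    new("ScreenCounts", se)
}

#' NormalizedCounts: normalized sgRNA abundances
#'
#' Same shape as \linkS4class{ScreenCounts} but holding the assay
#' \code{"normcounts"} of normalized reads per sgRNA (all values >= 1 by the
#' pseudo-count in the normalization formula; see [normalizeCounts()]).
#'
#' @aliases NormalizedCounts-class
#' @exportClass NormalizedCounts
setClass("NormalizedCounts", contains = "SummarizedExperiment")

setValidity("NormalizedCounts", function(object) {
    msg <- character()
    if (!("normcounts" %in% assayNames(object)))
        return("assay 'normcounts' is required")
    if (any(assay(object, "normcounts") < 1))
        msg <- c(msg, "normalized values must be >= 1 (pseudo-count floor)")
    if (!("gene" %in% colnames(rowData(object))))
        msg <- c(msg, "rowData must contain a 'gene' column")
    if (!("condition" %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain a 'condition' column")
    if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# VariantCohort
# ---------------------------------------------------------------------------

#' VariantCohort: per-sample somatic variant calls from a tumor cohort
#'
#' Holds one row per (sample, variant) observation with read-depth support,
#' plus a sample table carrying each sample's immune-pressure group label
#' (see [immuneGroups()]). Allele frequency is derived as
#' alt_depth / total_depth (0 when total_depth is 0).
#'
#' @slot calls `DataFrame` with columns `sample_id`, `group`, `gene`,
#'   `variant_id`, `annotation`, `alt_depth`, `total_depth`, `af`.
#' @slot samples `DataFrame` with columns `sample_id`, `group`.
#' @aliases VariantCohort-class
#' @exportClass VariantCohort
setClass("VariantCohort",
         representation(calls = "DataFrame", samples = "DataFrame"))

setValidity("VariantCohort", function(object) {
    msg <- character()
    need <- c("sample_id", "group", "gene", "variant_id", "annotation",
              "alt_depth", "total_depth", "af")
    calls <- object@calls
    if (!all(need %in% colnames(calls)))
        return(paste("calls must contain columns:",
                     paste(setdiff(need, colnames(calls)), collapse = ", ")))
    if (!all(calls$group %in% .IMMUNE_GROUPS))
        msg <- c(msg, paste("unknown group label(s):",
                 paste(unique(setdiff(calls$group, .IMMUNE_GROUPS)),
                       collapse = ", ")))
    if (!all(calls$annotation %in% .ANNOTATIONS))
        msg <- c(msg, "annotation must be one of the known classes")
    if (any(calls$alt_depth < 0) || any(calls$total_depth < 0))
        msg <- c(msg, "read depths must be non-negative")
    if (any(calls$alt_depth > calls$total_depth))
        msg <- c(msg, "alt_depth must not exceed total_depth")
    if (anyDuplicated(paste(calls$sample_id, calls$variant_id, sep = "\r")))
        msg <- c(msg, "duplicate (sample_id, variant_id) rows are not allowed")
    if (!all(calls$sample_id %in% object@samples$sample_id))
        msg <- c(msg, "every call must reference a known sample")
    if (length(msg)) msg else TRUE
})

#' Construct a VariantCohort
#'
#' @param calls data.frame (or DataFrame) with columns `sample_id`, `group`,
#'   `gene`, `variant_id`, `annotation`, `alt_depth`, `total_depth`. An `af`
#'   column, if present, is recomputed from the depths.
#' @param samples Optional data.frame with columns `sample_id`, `group`
#'   listing all cohort samples (including samples with no calls). Defaults
#'   to the samples observed in `calls`.
#' @return A \linkS4class{VariantCohort}.
#' @export
VariantCohort <- function(calls, samples = NULL) {
    calls <- DataFrame(as.data.frame(calls))
    calls$alt_depth <- as.integer(calls$alt_depth)
    calls$total_depth <- as.integer(calls$total_depth)
    calls$af <- ifelse(calls$total_depth > 0,
                       calls$alt_depth / calls$total_depth, 0)
    if (is.null(samples)) {
        keep <- !duplicated(calls$sample_id)
        samples <- DataFrame(sample_id = calls$sample_id[keep],
                             group = calls$group[keep])
    } else {
        samples <- DataFrame(as.data.frame(samples)[, c("sample_id", "group")])
    }
    new("VariantCohort", calls = calls, samples = samples)
}

# ---------------------------------------------------------------------------
# DispersionEstimate
# ---------------------------------------------------------------------------

#' DispersionEstimate: negative-binomial dispersion for a screen
#'
#' @slot phiCommon Common dispersion (squared coefficient of biological
#'   variation), estimated by conditional maximum likelihood.
#' @slot phiTagwise Optional per-guide dispersions shrunk toward the common
#'   value by an empirical-Bayes weighted likelihood (length 0 when not
#'   requested).
#' @slot shrinkageWeight Prior weight (in equivalent guides) used for the
#'   tagwise shrinkage.
#' @aliases DispersionEstimate-class
#' @exportClass DispersionEstimate
setClass("DispersionEstimate",
         representation(phiCommon = "numeric", phiTagwise = "numeric",
                        shrinkageWeight = "numeric"))

setValidity("DispersionEstimate", function(object) {
    if (length(object@phiCommon) != 1L || object@phiCommon < 0)
        return("phiCommon must be a single non-negative number")
    if (length(object@phiTagwise) && any(object@phiTagwise < 0))
        return("phiTagwise values must be non-negative")
    TRUE
})
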