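#' @include AllClasses.R
NULL

#' Allele frequency from read depths
#'
#' AF = depth of the alteration / total depth at the locus. A locus with
#' zero total depth carries no evidence of alteration and gets AF 0 (with a
#' warning).
#'
#' @param altDepth Alternate-allele read depth(s).
#' @param totalDepth Total read depth(s) at the locus.
#' @return Numeric vector of allele frequencies in \[0, 1\].
#' @export
#' @examples
#' computeAF(5, 50)    # 0.1
#' computeAF(30, 30)   # 1
computeAF <- function(altDepth, totalDepth) {
    if (any(altDepth < 0) || any(totalDepth < 0))
        stop("read depths must be non-negative")
    if (any(altDepth > totalDepth))
        stop("alt_depth must not exceed total_depth")
    zero <- totalDepth == 0
    if (any(zero))
        warning("total_depth of 0 at ", sum(zero),
                " locus/loci; AF set to 0")
    ifelse(zero, 0, altDepth / totalDepth)
}

#' Positive/negative mutation status from allele frequency
#'
#' A site is called positive when its AF reaches the threshold (default
#' 0.1). The boundary comparator is configurable: `"ge"` (the rule-table
#' convention, AF >= threshold) or `"gt"` (strict).
#'
#' @param af Allele frequency (vectorized), in \[0, 1\].
#' @param threshold Positivity threshold (default 0.1).
#' @param boundary `"ge"` (default) or `"gt"`.
#' @return Character vector, `"positive"` or `"negative"`.
#' @export
#' @examples
#' callStatus(c(0.1, 0.0999, 1))
callStatus <- function(af, threshold = 0.1, boundary = c("ge", "gt")) {
    boundary <- match.arg(boundary)
    if (any(af < 0) || any(af > 1)) stop("af must be in [0, 1]")
    pos <- if (boundary == "ge") af >= threshold else af > threshold
    ifelse(pos, "positive", "negative")
}

# variants x samples AF matrix; variants absent from a sample's table are 0
.afMatrix <- function(calls, samples) {
    vids <- unique(calls$variant_id)
    af <- matrix(0, nrow = length(vids), ncol = nrow(samples),
                 dimnames = list(vids, samples$sample_id))
    af[cbind(match(calls$variant_id, vids),
             match(calls$sample_id, samples$sample_id))] <- calls$af
    af
}

#' Classify hotspot immune-evasion candidate mutations
#'
#' Applies the cross-cohort rule table: a variant is reported iff it is
#' negative (AF below threshold) in every in vitro baseline and every
#' immunodeficient tumor, and positive in at least `minSupport` distinct
#' immunocompetent tumors. Reported variants are categorized
#' `PD1_dependent` when negative in every checkpoint-blockade tumor (both
#' the anti-PD-1 and anti-PD-L1 arms) and `PD1_independent` when positive
#' in at least one. A variant absent from a sample's table is treated as
#' negative there.
#'
#' @param cohort A [VariantCohort-class].
#' @param afThreshold Positivity threshold on AF (default 0.1).
#' @param minSupport Minimum number of distinct positive immunocompetent
#'   tumors (default 2).
#' @param boundary Boundary comparator passed to [callStatus()].
#' @return A `DataFrame` with one row per reported hotspot: `variant_id`,
#'   `gene`, `annotation`, `category`, `n_support`,
#'   `supporting_immunocompetent` and `positive_immunotherapy`
#'   (comma-separated sample IDs). The full variants x samples AF matrix of
#'   reported hotspots is attached as `metadata(x)$af`.
#' @export
classifyHotspots <- function(cohort, afThreshold = 0.1, minSupport = 2,
                             boundary = c("ge", "gt")) {
    boundary <- match.arg(boundary)
    stopifnot(is(cohort, "VariantCohort"))
    calls <- as.data.frame(variantCalls(cohort))
    samples <- as.data.frame(sampleInfo(cohort))
    nGrp <- table(factor(samples$group, levels = .IMMUNE_GROUPS))
    if (nGrp[["in_vitro"]] < 1)
        stop("cohort error: missing required group 'in_vitro'")
    if (nGrp[["immunodeficient"]] < 1)
        stop("cohort error: missing required group 'immunodeficient'")
    if (nGrp[["immunocompetent"]] < minSupport)
        stop("cohort error: fewer than ", minSupport,
             " samples in group 'immunocompetent'")
    af <- .afMatrix(calls, samples)
    pos <- if (boundary == "ge") af >= afThreshold else af > afThreshold
    grp <- samples$group
    baselineIdx <- grp %in% c("in_vitro", "immunodeficient")
    wtIdx <- grp == "immunocompetent"
    icbIdx <- grp %in% .ICB_GROUPS
    cleanBaseline <- rowSums(pos[, baselineIdx, drop = FALSE]) == 0
    nSupport <- rowSums(pos[, wtIdx, drop = FALSE])
    keep <- cleanBaseline & nSupport >= minSupport
    vids <- rownames(af)[keep]
    icbPos <- rowSums(pos[keep, icbIdx, drop = FALSE]) > 0
    meta <- calls[!duplicated(calls$variant_id),
                  c("variant_id", "gene", "annotation")]
    m <- meta[match(vids, meta$variant_id), ]
    supp <- vapply(which(keep), function(i)
        paste(samples$sample_id[wtIdx][pos[i, wtIdx]], collapse = ","), "")
    icbSupp <- vapply(which(keep), function(i)
        paste(samples$sample_id[icbIdx][pos[i, icbIdx]], collapse = ","), "")
    out <- DataFrame(variant_id = vids, gene = m$gene,
                     annotation = m$annotation,
                     category = ifelse(icbPos, "PD1_independent",
                                       "PD1_dependent"),
                     n_support = as.integer(nSupport[keep]),
                     supporting_immunocompetent = supp,
                     positive_immunotherapy = icbSupp)
    rownames(out) <- NULL
    metadata(out)$af <- af[keep, , drop = FALSE]
    metadata(out)$params <- list(afThreshold = afThreshold,
                                 minSupport = minSupport,
                                 boundary = boundary)
    out
}

#' Summarize a hotspot call table
#'
#' @param hotspots Output of [classifyHotspots()].
#' @return A list with `total`, `nGenes`, `byAnnotation` (named counts over
#'   the annotation classes) and `byCategory` (named counts over the two
#'   categories). Per-class counts sum to `total`.
#' @export
summarizeHotspots <- function(hotspots) {
    hs <- as.data.frame(hotspots)
    byAnn <- table(factor(hs$annotation, levels = .ANNOTATIONS))
    byCat <- table(factor(hs$category, levels = .CATEGORIES))
    list(total = nrow(hs),
         nGenes = length(unique(hs$gene)),
         byAnnotation = stats::setNames(as.integer(byAnn), names(byAnn)),
         byCategory = stats::setNames(as.integer(byCat), names(byCat)))
}
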