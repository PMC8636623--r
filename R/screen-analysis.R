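#' @include AllClasses.R
NULL

#' Normalize sgRNA read counts
#'
#' Normalized reads per sgRNA = (reads per sgRNA / total mapped reads in
#' the sample) x (max mapped-read count among all samples) + 1. The
#' pseudo-count of 1 floors every value at 1; within a sample the guide
#' ordering of the raw counts is preserved.
#'
#' @param x A [ScreenCounts-class] object.
#' @return A [NormalizedCounts-class] object with assay `"normcounts"`.
#' @export
#' @examples
#' m <- matrix(c(100, 900, 50, 950), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("a", "b")))
#' sc <- ScreenCounts(m, gene = c("A", "B"), condition = c("ref", "sel"))
#' assay(normalizeCounts(sc), "normcounts")
normalizeCounts <- function(x) {
    stopifnot(is(x, "ScreenCounts"))
    m <- assay(x, "counts")
    totals <- colSums(m)
    if (any(totals == 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(m)[totals == 0], collapse = ", "))
    norm <- sweep(m, 2L, totals, "/") * max(totals) + 1
    se <- SummarizedExperiment(assays = list(normcounts = norm),
                               rowData = rowData(x), colData = colData(x))
    new("NormalizedCounts", se)
}

# per-guide conditional log-likelihood of the NB dispersion, summed over
# within-condition replicate groups (equal effective sizes after
# normalization); y is a rounded guides x samples matrix
.condLogLik <- function(y, groups, phi) {
    r <- 1 / phi
    total <- 0
    for (idx in groups) {
        n <- length(idx)
        yg <- y[, idx, drop = FALSE]
        total <- total + rowSums(lgamma(yg + r)) - n * lgamma(r) +
            lgamma(n * r) - lgamma(rowSums(yg) + n * r)
    }
    total
}

#' Estimate negative-binomial dispersion from replicate screens
#'
#' The common dispersion maximizes the conditional likelihood of the
#' within-condition replicate counts given their sums (so the guide means
#' drop out). Optional tagwise dispersions maximize each guide's
#' conditional likelihood plus `shrinkageWeight` times the average
#' likelihood over all guides, shrinking noisy per-guide estimates toward
#' the common value (an empirical-Bayes weighted likelihood).
#'
#' @param x A [NormalizedCounts-class] (or [ScreenCounts-class]) object;
#'   values are rounded to integers for the conditional likelihood.
#' @param tagwise Also compute per-guide shrunk dispersions? Default FALSE.
#' @param shrinkageWeight Prior weight, in equivalent guides, pulling
#'   tagwise estimates toward the common value (default 10).
#' @param fallback Dispersion returned (with a warning) when no condition
#'   has replicates (default 0.1).
#' @return A [DispersionEstimate-class] object.
#' @export
estimateDispersion <- function(x, tagwise = FALSE, shrinkageWeight = 10,
                               fallback = 0.1) {
    y <- round(.assayMatrix(x))
    cond <- as.character(sampleConditions(x))
    groups <- split(seq_along(cond), cond)
    groups <- groups[lengths(groups) >= 2L]
    if (!length(groups)) {
        warning("no condition has >= 2 replicates; returning fallback ",
                "dispersion ", fallback)
        return(new("DispersionEstimate", phiCommon = fallback,
                   phiTagwise = numeric(), shrinkageWeight = shrinkageWeight))
    }
    allConst <- all(vapply(groups, function(idx)
        all(y[, idx] == y[, idx[1L]]), logical(1)))
    if (allConst)
        return(new("DispersionEstimate", phiCommon = 0,
                   phiTagwise = if (tagwise) rep(0, nrow(y)) else numeric(),
                   shrinkageWeight = shrinkageWeight))
    obj <- function(delta) -sum(.condLogLik(y, groups, delta / (1 - delta)))
    opt <- stats::optimize(obj, interval = c(1e-4, 0.95), tol = 1e-6)
    phiC <- opt$minimum / (1 - opt$minimum)
    phiT <- numeric()
    if (tagwise) {
        deltas <- exp(seq(log(1e-4), log(0.95), length.out = 60L))
        L <- vapply(deltas, function(d)
            .condLogLik(y, groups, d / (1 - d)), numeric(nrow(y)))
        score <- L + shrinkageWeight *
            matrix(colMeans(L), nrow(y), length(deltas), byrow = TRUE)
        best <- deltas[max.col(score, ties.method = "first")]
        phiT <- best / (1 - best)
    }
    new("DispersionEstimate", phiCommon = phiC, phiTagwise = phiT,
        shrinkageWeight = shrinkageWeight)
}

# two-sided conditional exact p-value for observing xa of s in group a,
# given replicate counts na/nb and NB dispersion phi (per replicate).
# With equal per-replicate means the conditional law of the group-a sum
# given the total is beta-binomial(s; na/phi, nb/phi); phi = 0 reduces to
# Binomial(s, na/(na+nb)). Two-sided by minimum likelihood: sum the
# probabilities of all outcomes no more likely than the observed one.
.condExactP <- function(xa, s, na, nb, phi) {
    if (s == 0) return(1)
    x <- 0:s
    lf <- if (phi == 0) {
        stats::dbinom(x, s, na / (na + nb), log = TRUE)
    } else {
        a <- na / phi
        b <- nb / phi
        lchoose(s, x) + lbeta(x + a, s - x + b) - lbeta(a, b)
    }
    min(1, sum(exp(lf[lf <= lf[xa + 1L] + 1e-8])))
}

#' Conditional negative-binomial exact test per sgRNA
#'
#' For each guide, normalized counts are summed within each condition into
#' pseudo-counts and the group-a sum is tested against the group-b sum
#' conditional on their total under a negative-binomial model with
#' dispersion `phi` (the adapted two-group exact test for overdispersed
#' counts). The two-sided p-value sums the conditional probabilities of all
#' splits at most as likely as the observed one; `phi = 0` reduces to the
#' conditional binomial test. Normalization makes the effective sizes of
#' the two groups proportional to their replicate numbers.
#'
#' @param x A [NormalizedCounts-class] object.
#' @param conditionA,conditionB Condition labels to compare; fold-changes
#'   are reported as B over A.
#' @param phi Per-replicate NB dispersion (e.g. [phiCommon()] of
#'   [estimateDispersion()]). Must be >= 0.
#' @return A `DataFrame` with one row per guide: `guide_id`, `gene`,
#'   `log2fc` (log2 of mean normalized abundance, B over A), `p_value`, and
#'   `direction` (`"enriched"` when log2fc > 0, else `"depleted"`).
#' @export
nbExactTest <- function(x, conditionA, conditionB, phi) {
    stopifnot(is(x, "NormalizedCounts"))
    if (length(phi) != 1L || is.na(phi) || phi < 0)
        stop("phi must be a single non-negative number")
    cond <- sampleConditions(x)
    ia <- which(cond == conditionA)
    ib <- which(cond == conditionB)
    if (!length(ia)) stop("condition not present: ", conditionA)
    if (!length(ib)) stop("condition not present: ", conditionB)
    m <- assay(x, "normcounts")
    ya <- m[, ia, drop = FALSE]
    yb <- m[, ib, drop = FALSE]
    sa <- round(rowSums(ya))
    sb <- round(rowSums(yb))
    log2fc <- log2(rowMeans(yb) / rowMeans(ya))
    p <- vapply(seq_len(nrow(m)), function(i)
        .condExactP(sa[i], sa[i] + sb[i], length(ia), length(ib), phi),
        numeric(1))
    DataFrame(guide_id = rownames(m), gene = geneMap(x),
              log2fc = log2fc, p_value = p,
              direction = ifelse(log2fc > 0, "enriched", "depleted"),
              row.names = NULL)
}

# alpha-RRA score for one gene: us = sorted guide percentiles, k guides;
# keep percentiles <= alpha and take the minimum beta order-statistic tail
.rraRho <- function(us, alpha) {
    k <- length(us)
    keep <- us <= alpha
    if (!any(keep)) return(1)
    j <- which(keep)
    min(stats::pbeta(us[j], j, k - j + 1))
}

#' Modified robust rank aggregation (alpha-RRA) over genes
#'
#' Guides are ranked by one-sided evidence in the chosen direction (the
#' two-sided p halved when the fold-change sign matches the direction,
#' 1 - p/2 otherwise) and converted to percentiles u = rank/m. For a gene
#' with k guides, the score rho is the minimum over its guides with
#' u <= alpha of Beta(j, k - j + 1) distribution values at the j-th
#' smallest percentile; genes with no guide below alpha score 1. The
#' permutation p-value compares each gene's rho with scores obtained by
#' randomly permuting the guide-to-gene assignment (preserving per-gene
#' guide counts).
#'
#' @param sgrnaResults Output of [nbExactTest()] (or any data.frame with
#'   `guide_id`, `gene`, `log2fc`, `p_value`).
#' @param alpha Percentile threshold below which guides count as
#'   significant (default 0.25).
#' @param nPerm Number of permutations (default 10000).
#' @param seed Integer seed for the permutations (required for
#'   reproducibility).
#' @param direction `"enriched"` or `"depleted"`: which selection direction
#'   the ranking rewards.
#' @return A `DataFrame` with one row per gene: `gene`, `rho`, `perm_p`
#'   (at least 1/(nPerm + 1)), `median_log2fc`, `n_guides` and
#'   `n_guides_passing_alpha`, sorted by `rho`.
#' @export
rraGeneScore <- function(sgrnaResults, alpha = 0.25, nPerm = 10000,
                         seed = 1, direction = c("enriched", "depleted")) {
    direction <- match.arg(direction)
    if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
    res <- as.data.frame(sgrnaResults)
    m <- nrow(res)
    matches <- if (direction == "enriched") res$log2fc > 0 else res$log2fc < 0
    oneSided <- ifelse(matches, res$p_value / 2, 1 - res$p_value / 2)
    u <- rank(oneSided, ties.method = "average") / m
    geneIdx <- split(seq_len(m), res$gene)
    kvec <- lengths(geneIdx)
    rhoObs <- vapply(geneIdx, function(ix) .rraRho(sort(u[ix]), alpha),
                     numeric(1))
    nPass <- vapply(geneIdx, function(ix) sum(u[ix] <= alpha), integer(1))
    medFC <- vapply(geneIdx, function(ix) stats::median(res$log2fc[ix]),
                    numeric(1))
    exceed <- .withSeed(seed, {
        U <- matrix(0, nPerm, m)
        for (i in seq_len(nPerm)) U[i, ] <- sample(u)
        cnt <- stats::setNames(integer(length(geneIdx)), names(geneIdx))
        for (k in unique(kvec)) {
            gsel <- names(geneIdx)[kvec == k]
            G <- length(gsel)
            idx <- unlist(geneIdx[gsel], use.names = FALSE)
            V <- U[, idx, drop = FALSE]
            arr <- array(V, dim = c(nPerm, k, G))
            M <- matrix(aperm(arr, c(1L, 3L, 2L)), nrow = nPerm * G, ncol = k)
            o <- order(row(M), M)
            Ms <- matrix(M[o], nrow = nrow(M), byrow = TRUE)
            rhoM <- rep(1, nrow(Ms))
            for (j in seq_len(k)) {
                v <- ifelse(Ms[, j] <= alpha,
                            stats::pbeta(Ms[, j], j, k - j + 1), 1)
                rhoM <- pmin(rhoM, v)
            }
            R <- matrix(rhoM, nPerm, G)
            cnt[gsel] <- colSums(R <= rep(rhoObs[gsel], each = nPerm) + 1e-12)
        }
        cnt
    })
    out <- DataFrame(gene = names(geneIdx), rho = unname(rhoObs),
                     perm_p = unname((1 + exceed) / (nPerm + 1)),
                     median_log2fc = unname(medFC),
                     n_guides = unname(kvec),
                     n_guides_passing_alpha = unname(nPass),
                     row.names = NULL)
    out[order(out$rho, out$perm_p), ]
}

#' Call screen hits at fold-change and p-value cut-offs
#'
#' Flags entries whose fold-change exceeds the cut in the stated direction
#' and whose (optionally BH-adjusted) p-value is below the cut. Two presets
#' match the screen read-outs: `"invivo"` (|FC| > 1.5, P < 0.05, both
#' directions) and `"coculture"` (FC > 1.4, P < 0.05, enrichment only).
#'
#' @param results Data.frame-like with a log2 fold-change column (`log2fc`
#'   or `median_log2fc`) and a p-value column (`p_value` or `perm_p`).
#' @param fcCut Fold-change cut-off (> 1), on the natural FC scale.
#' @param pCut P-value cut-off.
#' @param direction `"both"`, `"enriched"` or `"depleted"`.
#' @param adjust `"none"` (default, matching the screen read-outs) or
#'   `"BH"` for Benjamini-Hochberg adjustment before thresholding.
#' @param preset `"invivo"` or `"coculture"`; when given, overrides
#'   `fcCut`, `pCut` and `direction`.
#' @return The input as a `DataFrame` with a logical `hit` column appended.
#' @export
callHits <- function(results, fcCut = 1.5, pCut = 0.05,
                     direction = c("both", "enriched", "depleted"),
                     adjust = c("none", "BH"), preset = NULL) {
    adjust <- match.arg(adjust)
    if (!is.null(preset)) {
        preset <- match.arg(preset, c("invivo", "coculture"))
        if (preset == "invivo") {
            fcCut <- 1.5; pCut <- 0.05; direction <- "both"
        } else {
            fcCut <- 1.4; pCut <- 0.05; direction <- "enriched"
        }
    }
    direction <- match.arg(direction)
    if (fcCut <= 1) stop("fcCut must be > 1")
    res <- as.data.frame(results)
    fcCol <- intersect(c("log2fc", "median_log2fc"), colnames(res))[1]
    pCol <- intersect(c("p_value", "perm_p"), colnames(res))[1]
    if (is.na(fcCol) || is.na(pCol))
        stop("results must carry a fold-change and a p-value column")
    lfc <- res[[fcCol]]
    p <- res[[pCol]]
    if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
    passFC <- switch(direction,
                     both = 2^abs(lfc) > fcCut,
                     enriched = 2^lfc > fcCut,
                     depleted = 2^(-lfc) > fcCut)
    out <- DataFrame(res)
    out$hit <- passFC & p < pCut
    out
}

#' Per-guide log2 fold-change for competition assays
#'
#' log2 of the ratio of mean normalized abundance, condition B over A, per
#' guide; the read-out of a pooled in vivo competition assay.
#'
#' @param x A [NormalizedCounts-class] object.
#' @param conditionA,conditionB Condition labels (B over A).
#' @return `DataFrame` with `guide_id`, `gene`, `log2fc`.
#' @export
competitionLog2FC <- function(x, conditionA, conditionB) {
    stopifnot(is(x, "NormalizedCounts"))
    cond <- sampleConditions(x)
    ia <- which(cond == conditionA)
    ib <- which(cond == conditionB)
    if (!length(ia)) stop("condition not present: ", conditionA)
    if (!length(ib)) stop("condition not present: ", conditionB)
    m <- assay(x, "normcounts")
    DataFrame(guide_id = rownames(m), gene = geneMap(x),
              log2fc = log2(rowMeans(m[, ib, drop = FALSE]) /
                            rowMeans(m[, ia, drop = FALSE])),
              row.names = NULL)
}
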