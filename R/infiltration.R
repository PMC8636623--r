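#' @include AllClasses.R
NULL

#' Cytotoxic CD8 T cell infiltration score
#'
#' Per-sample arithmetic mean of the expression of the four cytotoxicity
#' markers CD8A, CD8B, GZMB and PRF1, a proxy for cytotoxic T lymphocyte
#' abundance in bulk expression data.
#'
#' @param expr Numeric matrix, genes x samples, with gene symbols as
#'   rownames (FPKM-like non-negative units).
#' @param genes Marker genes to average (default the four CD8 cytotoxicity
#'   markers).
#' @return Named numeric vector of per-sample scores.
#' @export
#' @examples
#' m <- matrix(1:8, nrow = 4,
#'             dimnames = list(c("CD8A", "CD8B", "GZMB", "PRF1"), c("s1", "s2")))
#' cytotoxicScore(m)
cytotoxicScore <- function(expr, genes = c("CD8A", "CD8B", "GZMB", "PRF1")) {
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
        stop("expression matrix is missing gene(s): ",
             paste(missing, collapse = ", "))
    colMeans(expr[genes, , drop = FALSE])
}

#' Stratify samples by an infiltration score percentile
#'
#' Labels a sample `"high"` when its score is strictly above the cohort's
#' percentile quantile (default the 75th percentile, computed with linear
#' interpolation) and `"low"` otherwise.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param percentile Quantile cut point in (0, 1) (default 0.75).
#' @return Character vector of `"high"`/`"low"` labels (named like
#'   `scores`).
#' @export
stratifyByScore <- function(scores, percentile = 0.75) {
    if (length(scores) < 4)
        stop("need at least 4 samples to stratify")
    q <- stats::quantile(scores, percentile, names = FALSE, type = 7)
    out <- ifelse(scores > q, "high", "low")
    names(out) <- names(scores)
    out
}

# all permutations of seq_len(n), as an n! x n matrix (n <= 9)
.allPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPerms(n - 1L)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        rest <- seq_len(n)[-i]
        out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
    }
    do.call(rbind, out)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Mid-ranks are used for ties. The two-sided p-value comes from the
#' t-approximation, except for tie-free samples of fewer than 10
#' observations where it is computed by exhaustive permutation of one
#' ranking.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `rho`, `p_value`, `n`, `method`, and `computable`
#'   (FALSE when either vector is constant, in which case `rho` and
#'   `p_value` are NA).
#' @export
spearmanAssoc <- function(x, y) {
    n <- length(x)
    if (length(y) != n) stop("x and y must have equal length")
    if (n < 3) stop("need at least 3 observations")
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]; n <- length(x)
    if (n < 3) stop("need at least 3 complete observations")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(rho = NA_real_, p_value = NA_real_, n = n,
                    method = "undefined", computable = FALSE))
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
    if (n < 10 && !ties) {
        P <- .allPerms(n)
        ryp <- matrix(ry[P], nrow(P), n)
        d2 <- rowSums((ryp - matrix(rx, nrow(P), n, byrow = TRUE))^2)
        rhoPerm <- 1 - 6 * d2 / (n * (n^2 - 1))
        p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
        method <- "exact permutation"
    } else {
        tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tstat), n - 2)
        method <- "t approximation"
    }
    list(rho = rho, p_value = min(1, p), n = n, method = method,
         computable = TRUE)
}

#' Pan-cohort correlation summary (volcano input)
#'
#' For each cohort (e.g. cancer type) computes the Spearman correlation of
#' one gene's expression against either another gene's expression, the
#' cytotoxic infiltration score, or a supplied per-sample vector (e.g. an
#' externally estimated T cell abundance), and flags significant negative
#' correlations (rho < 0 and p < 0.05).
#'
#' @param matrices Named list of gene x sample expression matrices, one per
#'   cohort.
#' @param geneX Gene whose expression is correlated.
#' @param target Either a gene symbol, the string `"cytotoxic_score"`, or a
#'   named list of per-sample numeric vectors (one per cohort).
#' @return data.frame with one row per usable cohort: `cohort_id`,
#'   `gene_x`, `target`, `n`, `rho`, `p_value`, `significant_negative`.
#'   Cohorts missing required genes are skipped with a warning.
#' @export
panCohortVolcano <- function(matrices, geneX, target = "cytotoxic_score") {
    stopifnot(length(matrices) > 0)
    if (is.null(names(matrices)))
        names(matrices) <- paste0("cohort", seq_along(matrices))
    rows <- list()
    targetLab <- if (is.character(target)) target else "supplied_vector"
    for (cid in names(matrices)) {
        expr <- matrices[[cid]]
        if (!(geneX %in% rownames(expr))) {
            warning("cohort ", cid, " is missing gene ", geneX, "; skipped")
            next
        }
        y <- if (is.list(target)) {
            target[[cid]]
        } else if (identical(target, "cytotoxic_score")) {
            sc <- tryCatch(cytotoxicScore(expr), error = function(e) NULL)
            if (is.null(sc)) {
                warning("cohort ", cid,
                        " is missing cytotoxic marker genes; skipped")
                next
            }
            sc
        } else {
            if (!(target %in% rownames(expr))) {
                warning("cohort ", cid, " is missing gene ", target,
                        "; skipped")
                next
            }
            expr[target, ]
        }
        res <- spearmanAssoc(as.numeric(expr[geneX, ]), as.numeric(y))
        rows[[cid]] <- data.frame(
            cohort_id = cid, gene_x = geneX, target = targetLab,
            n = res$n, rho = res$rho, p_value = res$p_value,
            significant_negative = isTRUE(res$computable) &&
                !is.na(res$rho) && res$rho < 0 && res$p_value < 0.05,
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Mutation prevalence as a printed percentage
#'
#' 100 x n_mutated / n_total, rounded half-up to one decimal place (the
#' convention used when quoting cohort prevalences such as 19/399 = 4.8%).
#'
#' @param nMutated Number of mutated cases.
#' @param nTotal Cohort size (> 0).
#' @return Percentage with one decimal.
#' @export
#' @examples
#' mutationPrevalence(19, 399)     # 4.8
#' mutationPrevalence(153, 10182)  # 1.5
mutationPrevalence <- function(nMutated, nTotal) {
    if (any(nTotal <= 0)) stop("nTotal must be > 0")
    if (any(nMutated < 0) || any(nMutated > nTotal))
        stop("nMutated must be between 0 and nTotal")
    floor(1000 * nMutated / nTotal + 0.5) / 10
}
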