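# Independent oracles used to validate the analysis implementations.
# These deliberately use naive loops / alternative formulations so they do
# not share code paths with the package.

# exhaustive evaluation of the hotspot rule table, one variant at a time
bruteHotspots <- function(calls, samples, threshold = 0.1, minSupport = 2,
                          boundary = "ge") {
    afOf <- function(sid, vid) {
        r <- calls[calls$sample_id == sid & calls$variant_id == vid, ]
        if (nrow(r) == 0 || r$total_depth == 0) 0
        else r$alt_depth / r$total_depth
    }
    isPos <- function(a) if (boundary == "ge") a >= threshold else a > threshold
    out <- list()
    for (vid in unique(calls$variant_id)) {
        cleanBase <- TRUE
        nSupp <- 0L
        nIcb <- 0L
        for (i in seq_len(nrow(samples))) {
            a <- afOf(samples$sample_id[i], vid)
            g <- samples$group[i]
            if (g %in% c("in_vitro", "immunodeficient") && isPos(a))
                cleanBase <- FALSE
            if (g == "immunocompetent" && isPos(a)) nSupp <- nSupp + 1L
            if (g %in% c("immunotherapy_aPD1", "immunotherapy_aPDL1") &&
                isPos(a)) nIcb <- nIcb + 1L
        }
        if (cleanBase && nSupp >= minSupport)
            out[[vid]] <- list(
                category = if (nIcb > 0) "PD1_independent" else "PD1_dependent",
                n_support = nSupp)
    }
    out
}

# conditional NB exact p by enumeration of negative-binomial products:
# P(x | s) = dnbinom(x; na*r, p) dnbinom(s-x; nb*r, p) / dnbinom(s; (na+nb)*r, p)
oracleCondNBP <- function(xa, s, na, nb, phi) {
    if (s == 0) return(1)
    x <- 0:s
    if (phi == 0) {
        f <- dbinom(x, s, na / (na + nb))
    } else {
        r <- 1 / phi
        mu <- s / (na + nb)
        top <- dnbinom(x, size = na * r, mu = na * mu) *
            dnbinom(s - x, size = nb * r, mu = nb * mu)
        bot <- dnbinom(s, size = (na + nb) * r, mu = (na + nb) * mu)
        f <- top / bot
    }
    min(1, sum(f[f <= f[xa + 1] * (1 + 1e-8)]))
}

# random small cohort with all required groups; some (sample, variant)
# rows are dropped to exercise the absent-row-is-negative convention
randomCohortTables <- function(seed, nVariants = 20, nIcb = 2) {
    set.seed(seed)
    grp <- c("in_vitro", rep("immunodeficient", 2),
             rep("immunocompetent", sample(2:4, 1)),
             sample(c("immunotherapy_aPD1", "immunotherapy_aPDL1"),
                    nIcb, replace = TRUE))
    samples <- data.frame(sample_id = sprintf("s%02d", seq_along(grp)),
                          group = grp, stringsAsFactors = FALSE)
    grid <- expand.grid(sample_id = samples$sample_id,
                        variant_id = sprintf("v%02d", seq_len(nVariants)),
                        stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) > 0.2, ]   # drop ~20% of rows
    n <- nrow(grid)
    total <- rpois(n, 60)
    alt <- rbinom(n, total, sample(c(0.01, 0.05, 0.12, 0.3), n, replace = TRUE))
    calls <- data.frame(
        sample_id = grid$sample_id,
        group = samples$group[match(grid$sample_id, samples$sample_id)],
        gene = paste0("G", match(grid$variant_id,
                                 sprintf("v%02d", seq_len(nVariants)))),
        variant_id = grid$variant_id,
        annotation = sample(annotationClasses(), n, replace = TRUE),
        alt_depth = alt, total_depth = total, stringsAsFactors = FALSE)
    list(calls = calls, samples = samples)
}

# recursive permutation enumeration, independent of the package's
oraclePerms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in oraclePerms(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

# exhaustive Spearman permutation p-value via cor() on every ordering
oracleSpearmanExactP <- function(x, y) {
    rhoObs <- cor(x, y, method = "spearman")
    perms <- oraclePerms(seq_along(y))
    hits <- vapply(perms, function(p)
        abs(cor(x, y[p], method = "spearman")) >= abs(rhoObs) - 1e-12,
        logical(1))
    mean(hits)
}

# small normalized-counts object built from a raw matrix
makeNorm <- function(m, gene, condition) {
    normalizeCounts(ScreenCounts(m, gene = gene, condition = condition))
}
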