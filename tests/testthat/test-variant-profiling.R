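# small hand-built cohort: 1 in vitro, 2 immunodeficient, 3 immunocompetent,
# 1 per ICB arm; AFs given per variant as named vectors
buildCohort <- function(afList, depth = 100) {
    samples <- data.frame(
        sample_id = c("iv1", "nd1", "nd2", "wt1", "wt2", "wt3", "pd1", "pdl1"),
        group = c("in_vitro", "immunodeficient", "immunodeficient",
                  rep("immunocompetent", 3),
                  "immunotherapy_aPD1", "immunotherapy_aPDL1"),
        stringsAsFactors = FALSE)
    rows <- list()
    for (vid in names(afList)) {
        af <- afList[[vid]]
        rows[[vid]] <- data.frame(
            sample_id = names(af),
            group = samples$group[match(names(af), samples$sample_id)],
            gene = paste0("gene_", vid), variant_id = vid,
            annotation = "missense",
            alt_depth = round(af * depth), total_depth = depth,
            stringsAsFactors = FALSE)
    }
    VariantCohort(do.call(rbind, rows), samples = samples)
}

test_that("allele frequency is alt depth over total depth", {
    expect_equal(computeAF(5, 50), 0.1)
    expect_equal(computeAF(0, 100), 0)
    expect_equal(computeAF(30, 30), 1)
    expect_warning(z <- computeAF(0, 0), "total_depth of 0")
    expect_equal(z, 0)
    expect_error(computeAF(10, 5), "exceed")
    expect_error(computeAF(-1, 5), "non-negative")
})

test_that("positivity boundary follows the rule-table convention", {
    expect_equal(callStatus(0.1), "positive")
    expect_equal(callStatus(0.0999), "negative")
    expect_equal(callStatus(1), "positive")
    expect_equal(callStatus(0.1, boundary = "gt"), "negative")
    expect_equal(callStatus(0.100001, boundary = "gt"), "positive")
    expect_error(callStatus(1.2), "af must be")
})

test_that("rule table classifies hotspots and categories", {
    cohort <- buildCohort(list(
        dep = c(wt1 = 0.25, wt2 = 0.31),                 # PD1_dependent
        ind = c(wt1 = 0.2, wt2 = 0.4, pd1 = 0.15),       # PD1_independent
        only1 = c(wt1 = 0.5),                            # support too low
        leaky = c(nd1 = 0.2, wt1 = 0.3, wt2 = 0.3),      # immunodeficient +
        boundary = c(wt1 = 0.1, wt2 = 0.1)))             # AF == threshold
    hs <- as.data.frame(classifyHotspots(cohort))
    expect_setequal(hs$variant_id, c("dep", "ind", "boundary"))
    expect_equal(hs$category[hs$variant_id == "dep"], "PD1_dependent")
    expect_equal(hs$category[hs$variant_id == "ind"], "PD1_independent")
    expect_equal(hs$positive_immunotherapy[hs$variant_id == "ind"], "pd1")
    expect_equal(hs$positive_immunotherapy[hs$variant_id == "dep"], "")
    expect_equal(hs$n_support[hs$variant_id == "ind"], 2L)
    # strict boundary drops the AF == 0.1 variant
    hsGt <- as.data.frame(classifyHotspots(cohort, boundary = "gt"))
    expect_setequal(hsGt$variant_id, c("dep", "ind"))
})

test_that("cohorts missing required groups or with duplicates are rejected", {
    cohort <- buildCohort(list(v = c(wt1 = 0.3, wt2 = 0.3)))
    noWT <- cohort
    calls <- as.data.frame(variantCalls(cohort))
    samples <- as.data.frame(sampleInfo(cohort))
    expect_error(classifyHotspots(
        VariantCohort(calls, samples[samples$group != "in_vitro", ])),
        "in_vitro")
    expect_error(classifyHotspots(cohort, minSupport = 5), "fewer than")
    expect_error(VariantCohort(rbind(calls, calls), samples), "duplicate")
})

test_that("classification matches the brute-force rule oracle", {
    for (seed in 1:60) {
        tabs <- randomCohortTables(seed)
        cohort <- VariantCohort(tabs$calls, tabs$samples)
        got <- as.data.frame(classifyHotspots(cohort))
        want <- bruteHotspots(tabs$calls, tabs$samples)
        expect_setequal(got$variant_id, as.character(names(want)))
        for (vid in names(want)) {
            expect_equal(got$category[got$variant_id == vid],
                         want[[vid]]$category)
            expect_equal(got$n_support[got$variant_id == vid],
                         want[[vid]]$n_support)
        }
    }
})

test_that("raising the AF threshold never adds hotspots (clean baselines)", {
    # support only shrinks as the threshold rises; on cohorts whose
    # baseline samples carry no alternate reads the exclusion rule cannot
    # newly release a variant, so the reported set shrinks monotonically
    tabs <- randomCohortTables(101, nVariants = 40)
    base <- tabs$calls$group %in% c("in_vitro", "immunodeficient")
    tabs$calls$alt_depth[base] <- 0L
    cohort <- VariantCohort(tabs$calls, tabs$samples)
    prev <- Inf
    for (thr in c(0.05, 0.1, 0.2, 0.3, 0.5)) {
        n <- nrow(classifyHotspots(cohort, afThreshold = thr))
        expect_lte(n, prev)
        prev <- n
    }
})

test_that("relabeling sample IDs leaves the hotspot set invariant", {
    tabs <- randomCohortTables(7)
    cohort <- VariantCohort(tabs$calls, tabs$samples)
    relab <- setNames(sprintf("X%02d", seq_len(nrow(tabs$samples))),
                      tabs$samples$sample_id)
    calls2 <- tabs$calls
    calls2$sample_id <- unname(relab[calls2$sample_id])
    samples2 <- tabs$samples
    samples2$sample_id <- unname(relab[samples2$sample_id])
    a <- as.data.frame(classifyHotspots(cohort))
    b <- as.data.frame(classifyHotspots(VariantCohort(calls2, samples2)))
    expect_identical(a[c("variant_id", "category", "n_support")],
                     b[c("variant_id", "category", "n_support")])
})

test_that("hotspot summaries tally annotation and category counts", {
    empty <- summarizeHotspots(S4Vectors::DataFrame(
        variant_id = character(), gene = character(),
        annotation = character(), category = character()))
    expect_equal(empty$total, 0)
    expect_true(all(empty$byAnnotation == 0))
    hs <- S4Vectors::DataFrame(
        variant_id = c("a", "b", "c"), gene = c("g1", "g1", "g2"),
        annotation = c("missense", "missense", "frameshift"),
        category = c("PD1_dependent", "PD1_dependent", "PD1_independent"))
    s <- summarizeHotspots(hs)
    expect_equal(s$total, 3)
    expect_equal(s$nGenes, 2)
    expect_equal(unname(s$byAnnotation[c("missense", "frameshift")]), c(2, 1))
    expect_equal(unname(s$byCategory), c(2, 1))
    expect_equal(sum(s$byAnnotation), s$total)
    expect_equal(sum(s$byCategory), s$total)
    # tallies agree with a direct count on classifier output
    sim <- simulateClonalCohort(cohortSimConfig(nPassengerSites = 20, seed = 3))
    hs2 <- classifyHotspots(sim$cohort)
    s2 <- summarizeHotspots(hs2)
    expect_equal(s2$total, nrow(hs2))
    expect_equal(unname(s2$byCategory["PD1_dependent"]),
                 sum(hs2$category == "PD1_dependent"))
})
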