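test_that("normalization reproduces the stated formula", {
    m <- matrix(c(100, 1e6 - 100, 50, 2e6 - 50), nrow = 2,
                dimnames = list(c("g1", "g2"), c("a", "b")))
    nrm <- makeNorm(m, gene = c("A", "B"), condition = c("ref", "sel"))
    v <- SummarizedExperiment::assay(nrm, "normcounts")
    expect_equal(v["g1", "a"], 100 / 1e6 * 2e6 + 1)  # 201
    expect_equal(v["g1", "b"], 50 / 2e6 * 2e6 + 1)   # 51
    # zero raw count floors at the pseudo-count
    m2 <- matrix(c(0, 1000, 10, 990), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
    v2 <- SummarizedExperiment::assay(
        makeNorm(m2, c("A", "B"), c("ref", "sel")), "normcounts")
    expect_equal(v2["g1", "a"], 1)
    # equal totals reduce to raw + 1
    m3 <- matrix(c(30, 70, 60, 40), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("a", "b")))
    v3 <- SummarizedExperiment::assay(
        makeNorm(m3, c("A", "B"), c("ref", "sel")), "normcounts")
    expect_equal(v3, m3 + 1)
})

test_that("normalization preserves within-sample ranks and flags empty samples", {
    set.seed(4)
    m <- matrix(rpois(300, 80), nrow = 50,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
    nrm <- makeNorm(m, gene = rep(sprintf("G%d", 1:10), each = 5),
                    condition = rep(c("ref", "sel"), each = 3))
    v <- SummarizedExperiment::assay(nrm, "normcounts")
    for (j in 1:6) expect_equal(order(v[, j]), order(m[, j]))
    expect_true(all(v >= 1))
    m0 <- m
    m0[, 2] <- 0L
    expect_error(ScreenCounts(m0, gene = rep(sprintf("G%d", 1:10), each = 5),
                              condition = rep(c("ref", "sel"), each = 3)),
                 "positive column total")
})

test_that("dispersion: zero for constant replicates, fallback without them", {
    m <- matrix(50, nrow = 20, ncol = 4,
                dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:4)))
    nrm <- makeNorm(m, gene = sprintf("G%d", 1:20),
                    condition = rep(c("a", "b"), each = 2))
    expect_equal(phiCommon(estimateDispersion(nrm)), 0)
    single <- makeNorm(m[, 1:2], gene = sprintf("G%d", 1:20),
                       condition = c("a", "b"))
    expect_warning(d <- estimateDispersion(single, fallback = 0.25),
                   "fallback")
    expect_equal(phiCommon(d), 0.25)
})

test_that("common dispersion agrees with an independent CML implementation", {
    skip_if_not_installed("edgeR")
    set.seed(11)
    y <- matrix(rnbinom(2000, mu = 150, size = 1 / 0.15), ncol = 4,
                dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:4)))
    nrm <- makeNorm(y, gene = sprintf("G%03d", 1:500),
                    condition = rep("a", 4))
    phi <- phiCommon(estimateDispersion(nrm))
    d <- edgeR::estimateCommonDisp(
        edgeR::DGEList(counts = y, group = rep("a", 4)))
    expect_equal(phi, d$common.dispersion, tolerance = 0.15)
    expect_equal(phi, 0.15, tolerance = 0.35)
})

test_that("tagwise dispersions shrink toward the common value", {
    set.seed(12)
    y <- matrix(rnbinom(1200, mu = 100, size = 1 / 0.2), ncol = 4,
                dimnames = list(sprintf("g%03d", 1:300), sprintf("s%d", 1:4)))
    nrm <- makeNorm(y, gene = sprintf("G%03d", 1:300),
                    condition = rep("a", 4))
    strong <- estimateDispersion(nrm, tagwise = TRUE, shrinkageWeight = 1e6)
    weak <- estimateDispersion(nrm, tagwise = TRUE, shrinkageWeight = 1)
    expect_length(phiTagwise(strong), 300)
    # infinite prior weight pins every guide at (essentially) one value
    expect_lt(diff(range(phiTagwise(strong))), 0.01)
    expect_gt(diff(range(phiTagwise(weak))), diff(range(phiTagwise(strong))))
})

test_that("exact test: symmetric null, binomial reduction, label swap", {
    m <- matrix(c(200, 800, 200, 800), nrow = 2,
                dimnames = list(c("g1", "g2"), c("a", "b")))
    nrm <- makeNorm(m, c("A", "B"), c("ref", "sel"))
    res <- as.data.frame(nbExactTest(nrm, "ref", "sel", phi = 0.1))
    expect_equal(res$log2fc, c(0, 0))
    expect_equal(res$p_value, c(1, 1))
    # phi = 0 equals the two-sided conditional binomial tail
    expect_equal(immunoedit:::.condExactP(3, 15, 1, 1, 0),
                 2 * pbinom(3, 15, 0.5))
    # swapping condition labels negates log2fc, keeps p
    set.seed(3)
    m2 <- matrix(rpois(40, 150), nrow = 10,
                 dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:4)))
    nrm2 <- makeNorm(m2, sprintf("G%d", 1:10), rep(c("x", "y"), each = 2))
    f <- as.data.frame(nbExactTest(nrm2, "x", "y", phi = 0.1))
    r <- as.data.frame(nbExactTest(nrm2, "y", "x", phi = 0.1))
    expect_equal(f$log2fc, -r$log2fc)
    expect_equal(f$p_value, r$p_value)
    expect_error(nbExactTest(nrm2, "x", "y", phi = -0.1), "non-negative")
    expect_error(nbExactTest(nrm2, "x", "zz", phi = 0.1), "not present")
})

test_that("exact test matches enumeration and edgeR on a sample grid", {
    for (phi in c(0, 0.1, 0.5)) {
        for (s in c(1, 7, 20, 50)) {
            for (a in unique(c(0, 1, s %/% 3, s %/% 2, s))) {
                expect_equal(immunoedit:::.condExactP(a, s, 1, 1, phi),
                             oracleCondNBP(a, s, 1, 1, phi),
                             tolerance = 1e-12)
                expect_equal(immunoedit:::.condExactP(a, s, 2, 3, phi),
                             oracleCondNBP(a, s, 2, 3, phi),
                             tolerance = 1e-12)
            }
        }
    }
    skip_if_not_installed("edgeR")
    set.seed(5)
    y1 <- matrix(rnbinom(60, mu = 120, size = 5), ncol = 3)
    y2 <- matrix(rnbinom(60, mu = 120, size = 5), ncol = 3)
    pEdgeR <- edgeR::exactTestBySmallP(y1, y2, dispersion = 0.2)
    pOwn <- vapply(seq_len(nrow(y1)), function(i)
        immunoedit:::.condExactP(round(sum(y1[i, ])),
                                 round(sum(y1[i, ])) + round(sum(y2[i, ])),
                                 3, 3, 0.2), numeric(1))
    expect_equal(pOwn, as.numeric(pEdgeR), tolerance = 1e-9)
})

test_that("alpha-RRA scores follow the beta order-statistic rule", {
    # 10 guides, distinct p-values; gene A holds the top-ranked guide
    res <- data.frame(guide_id = sprintf("g%02d", 1:10),
                      gene = c("A", rep(c("B", "C", "D"), each = 3)),
                      log2fc = rep(1, 10),
                      p_value = seq(0.01, 0.95, length.out = 10))
    rra <- as.data.frame(rraGeneScore(res, alpha = 0.25, nPerm = 100, seed = 1))
    expect_equal(rra$rho[rra$gene == "A"], 0.1)  # BetaCDF(0.1; 1, 1)
    # gene whose guides all rank above alpha scores 1
    expect_equal(rra$rho[rra$gene == "D"], 1)
    expect_equal(rra$n_guides_passing_alpha[rra$gene == "D"], 0L)
    # k = 2 gene: rho = min(pbeta(u1;1,2), pbeta(u2;2,1))
    res2 <- data.frame(guide_id = sprintf("g%d", 1:8),
                       gene = c("A", "A", rep("B", 6)),
                       log2fc = 1, p_value = (1:8) / 10)
    rra2 <- as.data.frame(rraGeneScore(res2, alpha = 1, nPerm = 100, seed = 1))
    u <- (1:2) / 8
    expect_equal(rra2$rho[rra2$gene == "A"],
                 min(pbeta(u[1], 1, 2), pbeta(u[2], 2, 1)))
})

test_that("RRA is rank-based: monotone p transforms leave rho unchanged", {
    set.seed(9)
    res <- data.frame(guide_id = sprintf("g%02d", 1:30),
                      gene = rep(sprintf("G%d", 1:6), each = 5),
                      log2fc = rnorm(30), p_value = runif(30))
    a <- rraGeneScore(res, nPerm = 50, seed = 2)
    res2 <- res
    res2$p_value <- res$p_value^2     # strictly monotone on (0, 1)
    b <- rraGeneScore(res2, nPerm = 50, seed = 2)
    expect_equal(a$rho, b$rho)
    expect_identical(a$gene, b$gene)
})

test_that("RRA permutation p-values are bounded, reproducible and exact", {
    set.seed(10)
    res <- data.frame(guide_id = sprintf("g%d", 1:6),
                      gene = c("A", "A", "B", "B", "C", "C"),
                      log2fc = rnorm(6), p_value = runif(6))
    a <- rraGeneScore(res, alpha = 0.5, nPerm = 2000, seed = 4)
    b <- rraGeneScore(res, alpha = 0.5, nPerm = 2000, seed = 4)
    expect_identical(a$perm_p, b$perm_p)
    expect_true(all(a$perm_p >= 1 / 2001 & a$perm_p <= 1))
    # exhaustive enumeration over all C(6,2)=15 unordered guide pairs
    u <- rank(ifelse(res$log2fc > 0, res$p_value / 2, 1 - res$p_value / 2)) / 6
    pairs <- combn(6, 2)
    for (g in c("A", "B", "C")) {
        obs <- a$rho[a$gene == g]
        exact <- mean(apply(pairs, 2, function(pr) {
            us <- sort(u[pr])
            keep <- us <= 0.5
            rho <- if (!any(keep)) 1 else
                min(pbeta(us[keep], which(keep), 2 - which(keep) + 1))
            rho <= obs + 1e-12
        }))
        mcse <- sqrt(exact * (1 - exact) / 2000)
        expect_lt(abs(a$perm_p[a$gene == g] - exact), 2 * mcse + 1e-3)
    }
})

test_that("hit calling applies fold-change and p cut-offs", {
    res <- data.frame(gene = c("a", "b", "c"),
                      log2fc = c(1, log2(1.45), 1),
                      p_value = c(0.01, 0.001, 0.2))
    hits <- callHits(res, preset = "invivo")
    expect_equal(hits$hit, c(TRUE, FALSE, FALSE))
    # depleted guides count under the two-sided in vivo preset
    dep <- data.frame(gene = "d", log2fc = -1.2, p_value = 0.01)
    expect_true(callHits(dep, preset = "invivo")$hit)
    expect_false(callHits(dep, preset = "coculture")$hit)
    # brute-force filter over random results
    set.seed(6)
    rnd <- data.frame(gene = sprintf("g%03d", 1:100),
                      log2fc = rnorm(100, 0, 1),
                      p_value = runif(100))
    got <- callHits(rnd, fcCut = 1.5, pCut = 0.05, direction = "both")$hit
    want <- abs(rnd$log2fc) > log2(1.5) & rnd$p_value < 0.05
    expect_identical(got, want)
    bh <- callHits(rnd, fcCut = 1.5, pCut = 0.05, adjust = "BH")$hit
    wantBH <- abs(rnd$log2fc) > log2(1.5) &
        p.adjust(rnd$p_value, "BH") < 0.05
    expect_identical(bh, wantBH)
    expect_error(callHits(rnd, fcCut = 0.9), "fcCut")
})

test_that("competition log2FC is the log ratio of mean normalized abundance", {
    # equal column totals: normalization reduces to raw + 1
    m <- matrix(c(100, 300, 100, 300, 200, 200, 200, 200), nrow = 2,
                dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
    nrm <- makeNorm(m, c("A", "B"), rep(c("pre", "post"), each = 2))
    res <- as.data.frame(competitionLog2FC(nrm, "pre", "post"))
    expect_equal(res$log2fc[res$guide_id == "g1"], log2(201 / 101))
    expect_equal(res$log2fc[res$guide_id == "g2"], log2(201 / 301))
    # proportional depth change alone gives log2FC 0 for every guide
    m2 <- matrix(c(100, 200, 100, 200, 200, 400, 200, 400), nrow = 2,
                 dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
    nrm2b <- makeNorm(m2, c("A", "B"), rep(c("pre", "post"), each = 2))
    res2 <- as.data.frame(competitionLog2FC(nrm2b, "pre", "post"))
    expect_equal(res2$log2fc, c(0, 0))
    # simulated fourfold effect at high depth and full efficacy
    sim <- simulateScreenCounts(screenSimConfig(
        nGenes = 20, guidesPerGene = 5, replicates = 3, sampleDepth = 4e6,
        nbDispersion = 0, efficacyShape1 = 1, efficacyShape2 = 0,
        geneEffect = list(post = c(Gene001 = 4)), seed = 13))
    nrm2 <- normalizeCounts(sim$counts)
    cl <- as.data.frame(competitionLog2FC(nrm2, "reference", "post"))
    gm <- geneMap(sim$counts)
    rel <- mean(cl$log2fc[gm == "Gene001"]) - mean(cl$log2fc[gm != "Gene001"])
    expect_equal(rel, 2, tolerance = 0.05)
})
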