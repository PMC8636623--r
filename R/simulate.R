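#' @include AllClasses.R
NULL

#' Default planted driver specification
#'
#' Builds a driver table for [simulateClonalCohort()]: a set of genes whose
#' mutant clone fraction is high only under T cell pressure. PD-1-dependent
#' drivers carry a high fraction in immunocompetent tumors but are purged in
#' both checkpoint-blockade arms; PD-1-independent drivers keep their high
#' fraction under blockade as well. All drivers are near-absent in cultured
#' cells and immunodeficient hosts.
#'
#' @param nDependent,nIndependent Number of planted drivers per category.
#' @param highFraction Clone fraction in the groups where a driver is
#'   selected (default 0.4).
#' @param lowFraction Residual clone fraction elsewhere (default 0.01).
#' @return data.frame with columns `gene`, `category`, and per-group
#'   fractions `f_in_vitro`, `f_immunodeficient`, `f_immunocompetent`,
#'   `f_immunotherapy`.
#' @export
defaultDriverSpec <- function(nDependent = 3, nIndependent = 3,
                              highFraction = 0.4, lowFraction = 0.01) {
    n <- nDependent + nIndependent
    if (n == 0L)
        return(data.frame(gene = character(), category = character(),
                          f_in_vitro = numeric(), f_immunodeficient = numeric(),
                          f_immunocompetent = numeric(),
                          f_immunotherapy = numeric()))
    dep <- rep(c(TRUE, FALSE), c(nDependent, nIndependent))
    data.frame(
        gene = c(sprintf("DrvDep%d", seq_len(nDependent)),
                 sprintf("DrvInd%d", seq_len(nIndependent))),
        category = ifelse(dep, "PD1_dependent", "PD1_independent"),
        f_in_vitro = rep(lowFraction, n),
        f_immunodeficient = rep(lowFraction, n),
        f_immunocompetent = rep(highFraction, n),
        f_immunotherapy = ifelse(dep, lowFraction, highFraction),
        stringsAsFactors = FALSE)
}

#' Configuration for the clonal tumor-cohort simulator
#'
#' Defaults mirror the study design the analysis assumes: one cultured
#' (in vitro) baseline, 10 immunodeficient tumors, 13 immunocompetent
#' tumors, and 8 checkpoint-blockade tumors split as evenly as possible
#' between the anti-PD-1 and anti-PD-L1 arms.
#'
#' @param nInVitro,nImmunodeficient,nImmunocompetent,nImmunotherapy Group
#'   sizes (defaults 1, 10, 13, 8).
#' @param nPassengerSites Number of passenger sites with low clone fraction
#'   in every group (default 50).
#' @param driverSpec Driver table as from [defaultDriverSpec()].
#' @param depthMean Mean total read depth per site (default 100 reads).
#' @param depthDispersion Negative-binomial dispersion of total depth
#'   (default 0.05; 0 gives Poisson depths).
#' @param afNoise SD of Gaussian jitter added to clone fractions per sample
#'   before binomial sampling, truncated to \[0, 1\] (default 0.005).
#' @param passengerFraction Clone fraction of passenger sites (default 0.01).
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `CohortSimConfig`.
#' @export
cohortSimConfig <- function(nInVitro = 1, nImmunodeficient = 10,
                            nImmunocompetent = 13, nImmunotherapy = 8,
                            nPassengerSites = 50,
                            driverSpec = defaultDriverSpec(),
                            depthMean = 100, depthDispersion = 0.05,
                            afNoise = 0.005, passengerFraction = 0.01,
                            seed = 1) {
    counts <- c(nInVitro, nImmunodeficient, nImmunocompetent, nImmunotherapy,
                nPassengerSites)
    .stopIfNot(all(counts >= 0) && all(counts == round(counts)),
               "group sizes and site counts must be non-negative integers")
    .stopIfNot(depthMean > 0, "depthMean must be > 0")
    .stopIfNot(depthDispersion >= 0, "depthDispersion must be >= 0")
    .stopIfNot(afNoise >= 0, "afNoise must be >= 0")
    .stopIfNot(passengerFraction >= 0 && passengerFraction <= 1,
               "passengerFraction must be in [0, 1]")
    driverSpec <- as.data.frame(driverSpec)
    fcols <- c("f_in_vitro", "f_immunodeficient", "f_immunocompetent",
               "f_immunotherapy")
    .stopIfNot(all(c("gene", "category", fcols) %in% colnames(driverSpec)),
               "driverSpec must have gene, category and per-group f_* columns")
    .stopIfNot(all(unlist(driverSpec[fcols]) >= 0) &&
               all(unlist(driverSpec[fcols]) <= 1),
               "clone fractions must be in [0, 1]")
    .stopIfNot(all(driverSpec$category %in% c(.CATEGORIES, "none")),
               "driver category must be PD1_dependent, PD1_independent or none")
    structure(list(nInVitro = nInVitro,
                   nImmunodeficient = nImmunodeficient,
                   nImmunocompetent = nImmunocompetent,
                   nImmunotherapy = nImmunotherapy,
                   nPassengerSites = nPassengerSites,
                   driverSpec = driverSpec,
                   depthMean = depthMean,
                   depthDispersion = depthDispersion,
                   afNoise = afNoise,
                   passengerFraction = passengerFraction,
                   seed = as.integer(seed)),
              class = "CohortSimConfig")
}

# deterministic site metadata (IDs, annotations) for a simulated cohort
.simSites <- function(config) {
    drv <- config$driverSpec
    nPsg <- config$nPassengerSites
    gene <- c(drv$gene, sprintf("Psg%03d", seq_len(nPsg)))
    category <- c(drv$category, rep("none", nPsg))
    n <- length(gene)
    bases <- c("A", "C", "G", "T")
    ref <- bases[(seq_len(n) - 1L) %% 4L + 1L]
    alt <- bases[seq_len(n) %% 4L + 1L]
    driverAnn <- c("missense", "splicing", "frameshift", "deletion")
    annotation <- c(driverAnn[(seq_len(nrow(drv)) - 1L) %% 4L + 1L],
                    .ANNOTATIONS[(seq_len(nPsg) - 1L) %% 5L + 1L])
    frac <- rbind(
        as.matrix(drv[, c("f_in_vitro", "f_immunodeficient",
                          "f_immunocompetent", "f_immunotherapy")]),
        matrix(config$passengerFraction, nrow = nPsg, ncol = 4L))
    colnames(frac) <- c("in_vitro", "immunodeficient", "immunocompetent",
                        "immunotherapy")
    data.frame(variant_id = sprintf("chr%d:%d:%s:%s",
                                    (seq_len(n) - 1L) %% 19L + 1L,
                                    10000L + 137L * seq_len(n), ref, alt),
               gene = gene, category = category, annotation = annotation,
               f_in_vitro = frac[, 1L], f_immunodeficient = frac[, 2L],
               f_immunocompetent = frac[, 3L], f_immunotherapy = frac[, 4L],
               stringsAsFactors = FALSE)
}

#' Simulate a tumor cohort under graded immune selection
#'
#' Generates per-sample variant tables with the clonal selection structure
#' the hotspot filter assumes: driver sites whose mutant clone fraction
#' depends on the host's T cell pressure, plus passenger sites with low
#' fraction everywhere. For each site and sample, total depth is drawn from
#' a negative binomial with mean `depthMean` and dispersion
#' `depthDispersion`, and alt depth binomially with the group-specific clone
#' fraction (after per-sample Gaussian jitter of SD `afNoise`).
#'
#' @param config A [cohortSimConfig()] object.
#' @return A list with elements `cohort` (a [VariantCohort-class]) and
#'   `truth` (data.frame of per-site ground truth: category and per-group
#'   clone fractions).
#' @export
#' @examples
#' sim <- simulateClonalCohort(cohortSimConfig(nPassengerSites = 5, seed = 7))
#' sim$cohort
#' head(sim$truth)
simulateClonalCohort <- function(config = cohortSimConfig()) {
    if (!inherits(config, "CohortSimConfig"))
        config <- do.call(cohortSimConfig, config)
    for (g in c("nInVitro", "nImmunodeficient", "nImmunocompetent",
                "nImmunotherapy"))
        if (config[[g]] < 1L)
            stop("configuration error: required group '", g, "' has no samples")
    nPD1 <- ceiling(config$nImmunotherapy / 2)
    nPDL1 <- config$nImmunotherapy - nPD1
    samples <- data.frame(
        sample_id = c(sprintf("invitro_%02d", seq_len(config$nInVitro)),
                      sprintf("nude_%02d", seq_len(config$nImmunodeficient)),
                      sprintf("wt_%02d", seq_len(config$nImmunocompetent)),
                      sprintf("apd1_%02d", seq_len(nPD1)),
                      if (nPDL1 > 0) sprintf("apdl1_%02d", seq_len(nPDL1))),
        group = c(rep("in_vitro", config$nInVitro),
                  rep("immunodeficient", config$nImmunodeficient),
                  rep("immunocompetent", config$nImmunocompetent),
                  rep("immunotherapy_aPD1", nPD1),
                  rep("immunotherapy_aPDL1", nPDL1)),
        stringsAsFactors = FALSE)
    sites <- .simSites(config)
    nSites <- nrow(sites)
    # both ICB arms share the immunotherapy clone fraction
    fracCol <- c(in_vitro = "f_in_vitro",
                 immunodeficient = "f_immunodeficient",
                 immunocompetent = "f_immunocompetent",
                 immunotherapy_aPD1 = "f_immunotherapy",
                 immunotherapy_aPDL1 = "f_immunotherapy")
    calls <- .withSeed(config$seed, {
        out <- vector("list", nrow(samples))
        for (i in seq_len(nrow(samples))) {
            grp <- samples$group[i]
            frac <- sites[[fracCol[[grp]]]]
            if (config$afNoise > 0)
                frac <- pmin(1, pmax(0, frac +
                             stats::rnorm(nSites, 0, config$afNoise)))
            total <- if (config$depthDispersion > 0)
                stats::rnbinom(nSites, mu = config$depthMean,
                               size = 1 / config$depthDispersion)
            else stats::rpois(nSites, config$depthMean)
            alt <- stats::rbinom(nSites, total, frac)
            out[[i]] <- data.frame(sample_id = samples$sample_id[i],
                                   group = grp, gene = sites$gene,
                                   variant_id = sites$variant_id,
                                   annotation = sites$annotation,
                                   alt_depth = alt, total_depth = total,
                                   stringsAsFactors = FALSE)
        }
        do.call(rbind, out)
    })
    truth <- sites[, c("variant_id", "gene", "category", "f_in_vitro",
                       "f_immunodeficient", "f_immunocompetent",
                       "f_immunotherapy")]
    list(cohort = VariantCohort(calls, samples), truth = truth)
}

#' Configuration for the pooled-screen count simulator
#'
#' Defaults mirror a targeted knockout library: 58 genes (including the
#' five checkpoint-pathway controls) with ten sgRNAs each, log-normal
#' baseline guide abundance, per-guide knockout efficacy drawn once from a
#' Beta distribution and reused across conditions, and negative-binomial
#' sequencing noise.
#'
#' @param nGenes Total number of genes including controls (default 58).
#' @param guidesPerGene Guides per gene (default 10).
#' @param controlGenes Control gene symbols included in the library
#'   (default Pdcd1, Cd274, Jak1, Jak2, B2m).
#' @param baselineSigma Log-scale SD of baseline guide abundance (0.5).
#' @param geneEffect Named list: condition -> named numeric vector of
#'   per-gene fold-changes (> 0) relative to the reference condition. Genes
#'   not named have effect 1.
#' @param efficacyShape1,efficacyShape2 Beta parameters of per-guide
#'   knockout efficacy on \[0, 1\] (default Beta(4, 1), mean 0.8).
#' @param sampleDepth Target sequencing depth per sample (default 3e5).
#' @param nbDispersion Negative-binomial dispersion of observed counts
#'   (default 0.2; 0 gives Poisson).
#' @param replicates Replicates per condition (default 8).
#' @param seed Integer seed fixing all randomness.
#' @return A validated list of class `ScreenSimConfig`.
#' @export
screenSimConfig <- function(nGenes = 58, guidesPerGene = 10,
                            controlGenes = c("Pdcd1", "Cd274", "Jak1",
                                             "Jak2", "B2m"),
                            baselineSigma = 0.5, geneEffect = list(),
                            efficacyShape1 = 4, efficacyShape2 = 1,
                            sampleDepth = 3e5, nbDispersion = 0.2,
                            replicates = 8, seed = 1) {
    .stopIfNot(nGenes >= length(controlGenes) && nGenes >= 1,
               "nGenes must cover at least the control genes")
    .stopIfNot(guidesPerGene >= 1, "guidesPerGene must be >= 1")
    .stopIfNot(sampleDepth > 0, "sampleDepth must be > 0")
    .stopIfNot(nbDispersion >= 0, "nbDispersion must be >= 0")
    .stopIfNot(replicates >= 1, "replicates must be >= 1")
    .stopIfNot(baselineSigma >= 0, "baselineSigma must be >= 0")
    genes <- c(controlGenes,
               sprintf("Gene%03d", seq_len(nGenes - length(controlGenes))))
    for (cond in names(geneEffect)) {
        fc <- geneEffect[[cond]]
        if (!length(fc)) next   # a condition with no perturbed gene is a null
        .stopIfNot(!is.null(names(fc)) && all(nzchar(names(fc))),
                   "geneEffect vectors must be named by gene")
        bad <- setdiff(names(fc), genes)
        if (length(bad))
            stop("configuration error: geneEffect references unknown gene(s): ",
                 paste(bad, collapse = ", "))
        .stopIfNot(all(fc > 0), "fold-changes must be > 0")
    }
    structure(list(nGenes = nGenes, guidesPerGene = guidesPerGene,
                   genes = genes, controlGenes = controlGenes,
                   baselineSigma = baselineSigma, geneEffect = geneEffect,
                   efficacyShape1 = efficacyShape1,
                   efficacyShape2 = efficacyShape2,
                   sampleDepth = sampleDepth, nbDispersion = nbDispersion,
                   replicates = replicates, seed = as.integer(seed)),
              class = "ScreenSimConfig")
}

#' Simulate pooled-screen sgRNA counts with planted gene effects
#'
#' Baseline guide abundances are log-normal; in a selected condition the
#' expected abundance of a guide is its baseline times
#' `fold_change(gene)^efficacy(guide)`, with efficacy drawn once per guide.
#' Observed counts are negative binomial around the expected proportion of
#' `sampleDepth`.
#'
#' @param config A [screenSimConfig()] object.
#' @return A list with elements `counts` (a [ScreenCounts-class] with
#'   conditions `reference` plus one per `geneEffect` entry) and `truth`
#'   (list: per-gene effects per condition, per-guide efficacy and baseline
#'   abundance).
#' @export
#' @examples
#' cfg <- screenSimConfig(nGenes = 6, controlGenes = "B2m", replicates = 2,
#'                        geneEffect = list(selected = c(Gene001 = 3)),
#'                        seed = 3)
#' sim <- simulateScreenCounts(cfg)
#' sim$counts
simulateScreenCounts <- function(config = screenSimConfig()) {
    if (!inherits(config, "ScreenSimConfig"))
        config <- do.call(screenSimConfig, config)
    genes <- config$genes
    guideGene <- rep(genes, each = config$guidesPerGene)
    guides <- paste0(guideGene, "_sg",
                     rep(seq_len(config$guidesPerGene), length(genes)))
    nGuides <- length(guides)
    conditions <- c("reference", names(config$geneEffect))
    .withSeed(config$seed, {
        baseline <- stats::rlnorm(nGuides, 0, config$baselineSigma)
        efficacy <- stats::rbeta(nGuides, config$efficacyShape1,
                                 config$efficacyShape2)
        cols <- list()
        condLab <- character()
        for (cond in conditions) {
            fc <- rep(1, nGuides)
            if (cond != "reference") {
                eff <- config$geneEffect[[cond]]
                idx <- match(guideGene, names(eff))
                fc <- ifelse(is.na(idx), 1, eff[idx])
            }
            w <- baseline * fc^efficacy
            mu <- w / sum(w) * config$sampleDepth
            for (r in seq_len(config$replicates)) {
                y <- if (config$nbDispersion > 0)
                    stats::rnbinom(nGuides, mu = mu,
                                   size = 1 / config$nbDispersion)
                else stats::rpois(nGuides, mu)
                cols[[length(cols) + 1L]] <- y
                condLab <- c(condLab, cond)
            }
        }
        m <- do.call(cbind, cols)
        rownames(m) <- guides
        colnames(m) <- sprintf("%s_r%d", condLab,
                               stats::ave(seq_along(condLab), condLab,
                                          FUN = seq_along))
        counts <- ScreenCounts(m, gene = guideGene, condition = condLab)
        truth <- list(geneEffect = config$geneEffect,
                      efficacy = stats::setNames(efficacy, guides),
                      baseline = stats::setNames(baseline, guides))
        list(counts = counts, truth = truth)
    })
}

#' Tumor volume from caliper measurements
#'
#' Estimates volume as (length x width^2) / 2, the standard formula for
#' subcutaneous engrafted tumors measured along the longest dimension and
#' its longest perpendicular.
#'
#' @param lengthMm Longest dimension, mm.
#' @param widthMm Longest perpendicular dimension, mm.
#' @return Volume in cubic millimetres. Vectorized.
#' @export
#' @examples
#' tumorVolume(10, 10)  # 500
#' tumorVolume(20, 10)  # 1000
tumorVolume <- function(lengthMm, widthMm) {
    if (any(lengthMm < 0) || any(widthMm < 0))
        stop("tumor dimensions must be non-negative")
    if (any(widthMm > lengthMm))
        warning("width exceeds length for some measurements; ",
                "expected length >= width")
    lengthMm * widthMm^2 / 2
}
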