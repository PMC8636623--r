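#' @include AllClasses.R
NULL

.VARIANT_COLS <- c("sample_id", "group", "gene", "variant_id", "annotation",
                   "alt_depth", "total_depth")

#' Read a per-sample variant table
#'
#' Reads a TSV of per-(sample, variant) calls (columns `sample_id`,
#' `group`, `gene`, `variant_id`, `annotation`, `alt_depth`,
#' `total_depth`), validates each row, and recomputes AF from the depths.
#' If the file carries an `af` column it is checked against the recomputed
#' value (tolerance 1e-6) with a warning on mismatch.
#'
#' @param path Path to the TSV.
#' @param samples Optional sample sheet (data.frame or TSV path with
#'   columns `sample_id`, `group`) listing all cohort samples.
#' @return A [VariantCohort-class].
#' @export
readVariantTable <- function(path, samples = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    missing <- setdiff(.VARIANT_COLS, colnames(tab))
    if (length(missing))
        stop("missing required column(s): ", paste(missing, collapse = ", "))
    for (col in c("alt_depth", "total_depth")) {
        v <- suppressWarnings(as.numeric(tab[[col]]))
        bad <- which(is.na(v) | v < 0 | v != round(v))
        if (length(bad))
            stop("malformed ", col, " at line ", bad[1] + 1L,
                 " of ", path)
        tab[[col]] <- as.integer(v)
    }
    bad <- which(tab$alt_depth > tab$total_depth)
    if (length(bad))
        stop("alt_depth exceeds total_depth at line ", bad[1] + 1L,
             " of ", path)
    bad <- which(!(tab$group %in% .IMMUNE_GROUPS))
    if (length(bad))
        stop("unknown group '", tab$group[bad[1]], "' at line ",
             bad[1] + 1L, " of ", path)
    unknownAnn <- !(tab$annotation %in% .ANNOTATIONS)
    if (any(unknownAnn)) {
        warning(sum(unknownAnn), " row(s) with unknown annotation class; ",
                "mapped to 'other'")
        tab$annotation[unknownAnn] <- "other"
    }
    if ("af" %in% colnames(tab)) {
        recomputed <- ifelse(tab$total_depth > 0,
                             tab$alt_depth / tab$total_depth, 0)
        off <- abs(as.numeric(tab$af) - recomputed) > 1e-6
        if (any(off, na.rm = TRUE))
            warning(sum(off, na.rm = TRUE),
                    " row(s) with AF inconsistent with depths; ",
                    "AF recomputed from depths")
    }
    if (is.character(samples) && length(samples) == 1L)
        samples <- utils::read.delim(samples, stringsAsFactors = FALSE)
    VariantCohort(tab[.VARIANT_COLS], samples = samples)
}

#' Write a variant cohort to TSV
#'
#' Columns `sample_id`, `group`, `gene`, `variant_id`, `annotation`,
#' `alt_depth`, `total_depth`, `af`, with AF formatted to 6 significant
#' digits for byte-stable output.
#'
#' @param cohort A [VariantCohort-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(cohort, path) {
    calls <- as.data.frame(variantCalls(cohort))
    calls$af <- .fmtNum(calls$af)
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read variant calls from a minimal VCF (allele depths from AD)
#'
#' Convenience adapter for single-sample VCFs whose genotype field carries
#' `AD` as ref,alt depths. Gene and annotation are taken from `GENE=` and
#' `ANN=` entries of INFO when present (annotation defaults to `"other"`).
#' Coordinates are used verbatim as `chrom:pos:ref:alt` variant IDs.
#'
#' @param path VCF path.
#' @param sampleId Sample identifier to assign.
#' @param group Immune-pressure group label for the sample.
#' @return data.frame of calls suitable for [VariantCohort()].
#' @export
readVariantVCF <- function(path, sampleId, group) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v, getINFO = TRUE)
    ad <- vcfR::extract.gt(v, element = "AD")[, 1L]
    parts <- strsplit(ad, ",", fixed = TRUE)
    ref <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    alt <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    info <- fix[, "INFO"]
    getInfo <- function(key) {
        has <- grepl(paste0("(^|;)", key, "="), info)
        out <- rep(NA_character_, length(info))
        out[has] <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2",
                        info[has])
        out
    }
    gene <- getInfo("GENE")
    ann <- getInfo("ANN")
    ann[is.na(ann) | !(ann %in% .ANNOTATIONS)] <- "other"
    gene[is.na(gene)] <- "NA"
    data.frame(sample_id = sampleId, group = group, gene = gene,
               variant_id = paste(fix[, "CHROM"], fix[, "POS"],
                                  fix[, "REF"], fix[, "ALT"], sep = ":"),
               annotation = ann, alt_depth = alt, total_depth = ref + alt,
               stringsAsFactors = FALSE)
}

#' Read an sgRNA count matrix with its sample sheet
#'
#' Accepts the count-table layout used by pooled-screen tools: columns
#' `sgRNA`, `gene`, then one integer column per sample. The sample sheet
#' (data.frame or TSV path) must carry `sample_id` and `condition`
#' (optionally `replicate`) for every count column.
#'
#' @param path Count TSV path.
#' @param samplesheet Sample sheet data.frame or TSV path.
#' @return A [ScreenCounts-class].
#' @export
readCountMatrix <- function(path, samplesheet) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!all(c("sgRNA", "gene") %in% colnames(tab)))
        stop("count table must start with 'sgRNA' and 'gene' columns")
    if (anyDuplicated(tab$sgRNA))
        stop("duplicated guide ID(s): ",
             paste(unique(tab$sgRNA[duplicated(tab$sgRNA)]), collapse = ", "))
    if (is.character(samplesheet) && length(samplesheet) == 1L)
        samplesheet <- utils::read.delim(samplesheet, stringsAsFactors = FALSE)
    samplesheet <- as.data.frame(samplesheet)
    if (!all(c("sample_id", "condition") %in% colnames(samplesheet)))
        stop("sample sheet must carry 'sample_id' and 'condition'")
    sampleCols <- setdiff(colnames(tab), c("sgRNA", "gene"))
    unknown <- setdiff(sampleCols, samplesheet$sample_id)
    if (length(unknown))
        stop("sample column(s) not in sample sheet: ",
             paste(unknown, collapse = ", "))
    samplesheet <- samplesheet[match(sampleCols, samplesheet$sample_id), ]
    m <- as.matrix(tab[sampleCols])
    if (any(is.na(m)) || any(m != round(m)) || any(m < 0))
        stop("counts must be non-negative integers")
    rownames(m) <- tab$sgRNA
    ScreenCounts(m, gene = tab$gene, condition = samplesheet$condition,
                 replicate = samplesheet$replicate)
}

#' Write an sgRNA count matrix and sample sheet to TSV
#'
#' @param x A [ScreenCounts-class].
#' @param path Count TSV path (`sgRNA`, `gene`, one column per sample).
#' @param samplesheetPath Optional path for the sample sheet TSV
#'   (`sample_id`, `condition`, `replicate`).
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(x, path, samplesheetPath = NULL) {
    m <- assay(x, "counts")
    tab <- data.frame(sgRNA = rownames(m),
                      gene = as.character(rowData(x)$gene),
                      m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(samplesheetPath)) {
        sheet <- data.frame(sample_id = colnames(m),
                            condition = as.character(colData(x)$condition),
                            replicate = as.integer(colData(x)$replicate))
        utils::write.table(sheet, samplesheetPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

.writeDF <- function(df, path) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1)) &
        !vapply(df, is.integer, logical(1))
    df[num] <- lapply(df[num], .fmtNum)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Run the full simulate-profile-screen pipeline
#'
#' Simulates a clonal tumor cohort and a pooled screen, profiles hotspot
#' mutations, runs the screen statistics (normalization, dispersion, NB
#' exact test, alpha-RRA, hit calling), and writes all tables plus a JSON
#' manifest of parameters and seeds to `outDir`. All randomness derives
#' from `seed`, so a rerun with the same configuration is byte-identical.
#'
#' @param outDir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param cohortConfig A [cohortSimConfig()]; its `seed` is overridden by
#'   `seed`.
#' @param screenConfig A [screenSimConfig()]; its `seed` is overridden by
#'   `seed + 1`.
#' @param stages Subset of `c("simulate", "profile", "screen")` to run
#'   (profiling and screening require "simulate" outputs and are run on
#'   the in-memory objects).
#' @param afThreshold,minSupport Hotspot filter parameters.
#' @param contrast Length-2 character: reference and selected condition of
#'   the screen comparison.
#' @param preset Hit-calling preset (see [callHits()]).
#' @param alpha,nPerm RRA parameters.
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `hotspots`, `summary`, `counts`, `guideResults`, `geneResults`,
#'   `manifest`).
#' @export
runPipeline <- function(outDir, seed = 1,
                        cohortConfig = cohortSimConfig(),
                        screenConfig = screenSimConfig(
                            geneEffect = list(selected = c(Gene001 = 3))),
                        stages = c("simulate", "profile", "screen"),
                        afThreshold = 0.1, minSupport = 2,
                        contrast = c("reference", "selected"),
                        preset = "invivo", alpha = 0.25, nPerm = 1000) {
    stages <- match.arg(stages, several.ok = TRUE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logStage <- function(stage, ...)
        message(sprintf("[%s] %s", stage, paste0(...)))
    result <- list()
    cohortConfig$seed <- as.integer(seed)
    screenConfig$seed <- as.integer(seed) + 1L
    manifest <- list(package = "immunoedit",
                     version = as.character(utils::packageVersion("immunoedit")),
                     seed = as.integer(seed), stages = stages,
                     parameters = list(
                         afThreshold = afThreshold, minSupport = minSupport,
                         contrast = contrast, preset = preset,
                         alpha = alpha, nPerm = nPerm,
                         cohort = cohortConfig[setdiff(names(cohortConfig),
                                                       "driverSpec")],
                         screen = screenConfig[setdiff(names(screenConfig),
                                                       c("geneEffect",
                                                         "genes"))]))
    if ("simulate" %in% stages) {
        logStage("simulate", "cohort and screen counts, seed ", seed)
        sim <- simulateClonalCohort(cohortConfig)
        result$cohort <- sim$cohort
        result$cohortTruth <- sim$truth
        writeVariantTable(sim$cohort, file.path(outDir, "variants.tsv"))
        utils::write.table(
            as.data.frame(sampleInfo(sim$cohort)),
            file.path(outDir, "cohort_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(sim$truth, file.path(outDir, "cohort_truth.json"),
                             digits = NA, auto_unbox = TRUE)
        scr <- simulateScreenCounts(screenConfig)
        result$counts <- scr$counts
        writeCountMatrix(scr$counts, file.path(outDir, "counts.tsv"),
                         file.path(outDir, "screen_samples.tsv"))
        jsonlite::write_json(
            list(geneEffect = scr$truth$geneEffect,
                 efficacy = as.list(scr$truth$efficacy)),
            file.path(outDir, "screen_truth.json"),
            digits = NA, auto_unbox = TRUE)
        logStage("simulate", nrow(variantCalls(sim$cohort)),
                 " variant rows, ", nrow(scr$counts), " guides")
    }
    if ("profile" %in% stages) {
        if (is.null(result$cohort))
            stop("stage 'profile' requires stage 'simulate'")
        logStage("profile", "AF threshold ", afThreshold,
                 ", min support ", minSupport)
        hs <- classifyHotspots(result$cohort, afThreshold = afThreshold,
                               minSupport = minSupport)
        result$hotspots <- hs
        result$summary <- summarizeHotspots(hs)
        .writeDF(hs, file.path(outDir, "hotspots.tsv"))
        jsonlite::write_json(result$summary,
                             file.path(outDir, "hotspot_summary.json"),
                             digits = NA, auto_unbox = TRUE)
        logStage("profile", result$summary$total, " hotspots")
    }
    if ("screen" %in% stages) {
        if (is.null(result$counts))
            stop("stage 'screen' requires stage 'simulate'")
        logStage("screen", "contrast ", contrast[1], " vs ", contrast[2])
        norm <- normalizeCounts(result$counts)
        disp <- estimateDispersion(norm)
        gres <- nbExactTest(norm, contrast[1], contrast[2],
                            phi = phiCommon(disp))
        rra <- rraGeneScore(gres, alpha = alpha, nPerm = nPerm,
                            seed = as.integer(seed) + 2L,
                            direction = "enriched")
        hits <- callHits(rra, preset = preset)
        result$guideResults <- gres
        result$geneResults <- hits
        result$dispersion <- disp
        .writeDF(gres, file.path(outDir, "guide_results.tsv"))
        .writeDF(hits, file.path(outDir, "gene_results.tsv"))
        manifest$dispersion <- phiCommon(disp)
        logStage("screen", sum(hits$hit), " gene hits, phi ",
                 signif(phiCommon(disp), 4))
    }
    result$manifest <- manifest
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    invisible(result)
}
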