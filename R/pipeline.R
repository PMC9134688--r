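#' Study run configuration
#'
#' Builds the configuration list driving [runFullStudy()] and the individual
#' pipeline stages. Defaults mirror the study acquisition and analysis
#' settings: 30 directions at b = 970 s/mm^2 plus one b = 0 volume, 0.01 FA
#' histogram bins (fixed), 6 subjects per group, FDR level q = 0.1, and the
#' Burr-fit median as the histogram-shift descriptor.
#'
#' @param outDir output directory; every stage reads and writes its declared
#'   file artifacts below this directory.
#' @param seed master integer seed; stage-level seeds are derived from it.
#' @param nPerGroup DTI subjects per group.
#' @param snr phantom b0 signal-to-noise ratio.
#' @param rdReduction treated-group radial-diffusivity reduction (0 = null
#'   study with no treatment effect anywhere).
#' @param nDirections,bValue,nB0 acquisition scheme settings.
#' @param q false-discovery-rate level for regional and IHC comparisons.
#' @param descriptor Burr descriptor tested for the histogram shift.
#' @param mbp list: `ages`, `effect` (days of midpoint shift; scaled by the
#'   effect switch below), `noiseCv`, `nPerCell`.
#' @param plate list: `standardTop`, `nSerial`, `dilutionFactor`,
#'   `curveParams`, `noiseCv`, `sampleDilution`.
#' @param ihc list: `ages`, `nPerCell`, `shape`, `fgIntensity`,
#'   `bgIntensity`, `noiseSd`, `threshold`, `maxFraction`.
#' @param teeth list: `nPerGroup`, `pEruption` (named per group).
#' @param groups group names; the second is the treated group.
#' @return a list of class `"studyConfig"`.
#' @export
studyConfig <- function(outDir, seed = 1L,
                        nPerGroup = 6L, snr = 25, rdReduction = 0.25,
                        nDirections = 30L, bValue = 970, nB0 = 1L,
                        q = 0.1, descriptor = "median",
                        mbp = list(), plate = list(), ihc = list(),
                        teeth = list(), groups = c("vehicle", "T4")) {
    if (q <= 0 || q >= 1) stop("'q' must lie in (0, 1)")
    mbpDef <- list(ages = 3:11, effect = 2, noiseCv = 0.15, nPerCell = 6L)
    plateDef <- list(standardTop = 100, nSerial = 7L, dilutionFactor = 2,
        curveParams = c(lower = 0.05, upper = 2, mid = 15, slope = 1.2),
        noiseCv = 0.02, sampleDilution = 4)
    ihcDef <- list(ages = c(5L, 7:11), nPerCell = 6L, shape = c(80L, 100L),
        fgIntensity = 200, bgIntensity = 50, noiseSd = 10, threshold = 75,
        maxFraction = 0.35, subjectCv = 0.15)
    teethDef <- list(nPerGroup = 11L, pEruption = c(9 / 11, 1 / 11))
    cfg <- list(outDir = outDir, seed = as.integer(seed),
        nPerGroup = as.integer(nPerGroup), snr = snr,
        rdReduction = rdReduction, nDirections = as.integer(nDirections),
        bValue = bValue, nB0 = as.integer(nB0), q = q,
        descriptor = match.arg(descriptor, c("median", "mean", "mode")),
        mbp = utils::modifyList(mbpDef, mbp),
        plate = utils::modifyList(plateDef, plate),
        ihc = utils::modifyList(ihcDef, ihc),
        teeth = utils::modifyList(teethDef, teeth),
        groups = groups)
    class(cfg) <- "studyConfig"
    cfg
}

#' Read a study configuration from a YAML file
#'
#' Keys absent from the file keep the [studyConfig()] defaults. `seed` and
#' `outDir` given as arguments override the file.
#'
#' @param path YAML file with any subset of the [studyConfig()] arguments.
#' @param outDir,seed optional overrides.
#' @return a list of class `"studyConfig"`.
#' @export
readStudyConfig <- function(path, outDir = NULL, seed = NULL) {
    y <- yaml::read_yaml(path)
    if (!is.null(outDir)) y$outDir <- outDir
    if (!is.null(seed)) y$seed <- seed
    if (is.null(y$outDir)) stop("config must provide 'outDir'")
    if (!is.null(y$plate$curveParams))
        y$plate$curveParams <- unlist(y$plate$curveParams)
    if (!is.null(y$teeth$pEruption))
        y$teeth$pEruption <- unlist(y$teeth$pEruption)
    do.call(studyConfig, y)
}

## Per-stage seeds derived from the master seed; offsets keep the stages
## independently reproducible while staying inside 32-bit integer range.
stageSeed <- function(cfg, k)
    as.integer((as.numeric(cfg$seed) * 97 + k) %% .Machine$integer.max)

studyPath <- function(cfg, ...) file.path(cfg$outDir, ...)

writeTable <- function(df, path) {
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

ihcTrueFraction <- function(age, treated, cfg) {
    shift <- ifelse(treated, cfg$mbp$effect, 0)
    cfg$ihc$maxFraction * stats::plogis((age - (10 - shift)) / 1.5)
}

#' Pipeline stages
#'
#' Each stage reads only the file artifacts written by earlier stages below
#' `outDir` and writes its own, so the pipeline can be re-run from any
#' stage. [runFullStudy()] chains them.
#'
#' * `stageSimulate()`: scheme (`bvals`/`bvecs`), per-subject DWI NIfTI,
#'   region-label NIfTI, subject metadata, developmental MBP table, ELISA
#'   plate records, stained-section TIFFs and the tooth-eruption table.
#' * `stageFitDTI()`: tensor fit and FA/MD/AD/RD NIfTI maps per subject.
#' * `stageHistogram()`: forebrain FA histograms, Burr fits, group-average
#'   histograms and the Welch histogram-shift test.
#' * `stageRegionalStats()`: regional means and Student t comparisons with
#'   two-stage FDR per metric.
#' * `stageMBP()`: standard-curve fit, sample back-quantification, the
#'   developmental two-way ANOVA with Tukey post hocs, and IHC percent-area
#'   scoring with both per-day t/FDR and ANOVA treatments.
#' * `stageCorrelate()`: Pearson correlation of plate-quantified MBP with
#'   Burr-fit medians over the DTI subjects.
#' * `stageReport()`: plain-markdown study report with a provenance block.
#'
#' @param cfg a [studyConfig()] list.
#' @return each stage invisibly returns the paths it wrote;
#' @name pipelineStages
NULL

#' @rdname pipelineStages
#' @export
stageSimulate <- function(cfg) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(unclass(cfg), studyPath(cfg, "config.yaml"))
    scheme <- makeScheme(cfg$nDirections, cfg$bValue, cfg$nB0)
    writeScheme(scheme, studyPath(cfg, "bvals"), studyPath(cfg, "bvecs"))

    groups <- structure(rep(cfg$nPerGroup, 2L), names = cfg$groups)
    spec <- defaultPhantomSpec(groups = groups,
        rdReduction = cfg$rdReduction, snr = cfg$snr,
        seed = stageSeed(cfg, 1L))
    sim <- simulateDWI(spec, scheme)
    dir.create(studyPath(cfg, "dwi"), showWarnings = FALSE)
    for (id in names(sim$subjects))
        RNifti::writeNifti(RNifti::asNifti(sim$subjects[[id]]),
            studyPath(cfg, "dwi", paste0(id, "_dwi.nii.gz")))
    RNifti::writeNifti(RNifti::asNifti(sim$labels * 1),
        studyPath(cfg, "dwi", "labels.nii.gz"))
    meta <- data.frame(subject = names(sim$truth@groupAssignment),
        group = unname(sim$truth@groupAssignment), PND = 10L,
        stringsAsFactors = FALSE)
    writeTable(meta, studyPath(cfg, "metadata.csv"))
    wm <- sim$regionNames %in% wmRegionNames()
    writeTable(data.frame(label = seq_along(sim$regionNames)[wm],
        region = sim$regionNames[wm]), studyPath(cfg, "regions.csv"))

    mbpTab <- simulateMBPDevelopment(ages = cfg$mbp$ages,
        groups = cfg$groups, effect = cfg$mbp$effect,
        noiseCv = cfg$mbp$noiseCv, nPerCell = cfg$mbp$nPerCell,
        seed = stageSeed(cfg, 2L), treatedGroup = cfg$groups[2])
    writeTable(mbpTab, studyPath(cfg, "mbp", "mbp_development.csv"))

    # lysates of the DTI-scanned pups, sampled the day after the scan,
    # measured on the simulated plate and later joined with the Burr medians
    set.seed(stageSeed(cfg, 3L))
    treated <- meta$group == cfg$groups[2]
    neat <- pmax(0, mbpMeanCurve(11, effect = cfg$mbp$effect,
            treated = treated) *
        (1 + rnorm(nrow(meta), 0, cfg$mbp$noiseCv)))
    plateSamples <- data.frame(id = meta$subject,
        conc = neat / cfg$plate$sampleDilution,
        dilution = cfg$plate$sampleDilution)
    plateTab <- simulatePlate(standardTop = cfg$plate$standardTop,
        nSerial = cfg$plate$nSerial,
        dilutionFactor = cfg$plate$dilutionFactor,
        curveParams = cfg$plate$curveParams, noiseCv = cfg$plate$noiseCv,
        samples = plateSamples, seed = stageSeed(cfg, 4L))
    writeTable(plateTab, studyPath(cfg, "mbp", "plate.csv"))

    dir.create(studyPath(cfg, "ihc"), showWarnings = FALSE)
    ihcMeta <- expand.grid(i = seq_len(cfg$ihc$nPerCell),
        group = cfg$groups, PND = cfg$ihc$ages, stringsAsFactors = FALSE)
    recs <- vector("list", nrow(ihcMeta))
    # between-animal variability of the stained fraction, drawn up front
    # because the image simulator reseeds the stream per image
    set.seed(stageSeed(cfg, 6L))
    cellFrac <- ihcTrueFraction(ihcMeta$PND, ihcMeta$group == cfg$groups[2],
        cfg)
    subjFrac <- pmin(1, pmax(0,
        cellFrac * (1 + rnorm(nrow(ihcMeta), 0, cfg$ihc$subjectCv))))
    for (j in seq_len(nrow(ihcMeta))) {
        g <- ihcMeta$group[j]; a <- ihcMeta$PND[j]; i <- ihcMeta$i[j]
        frac <- subjFrac[j]
        im <- simulateIHCImage(shape = cfg$ihc$shape,
            positiveFraction = frac, fgIntensity = cfg$ihc$fgIntensity,
            bgIntensity = cfg$ihc$bgIntensity, noiseSd = cfg$ihc$noiseSd,
            seed = stageSeed(cfg, 100L + j))
        f <- sprintf("%s_P%02d_%d", g, a, i)
        writeIHCImage(im$image, studyPath(cfg, "ihc", paste0(f, ".tif")))
        writeIHCMask(im$mask, studyPath(cfg, "ihc", paste0(f, "_mask.tif")))
        recs[[j]] <- data.frame(file = f, subject = f, group = g, PND = a,
            trueFraction = im$trueFraction, stringsAsFactors = FALSE)
    }
    writeTable(do.call(rbind, recs), studyPath(cfg, "ihc", "ihc_metadata.csv"))

    teethTab <- simulateTeeth(
        nPerGroup = structure(rep(cfg$teeth$nPerGroup, 2L),
            names = rev(cfg$groups)),
        pEruption = structure(cfg$teeth$pEruption, names = rev(cfg$groups)),
        seed = stageSeed(cfg, 5L))
    writeTable(data.frame(group = rownames(teethTab),
        erupted = teethTab[, "erupted"],
        notErupted = teethTab[, "notErupted"]),
        studyPath(cfg, "teeth.csv"))
    invisible(cfg$outDir)
}

readMetadata <- function(cfg)
    utils::read.csv(studyPath(cfg, "metadata.csv"), stringsAsFactors = FALSE)

#' @rdname pipelineStages
#' @export
stageFitDTI <- function(cfg) {
    scheme <- readScheme(studyPath(cfg, "bvals"), studyPath(cfg, "bvecs"))
    meta <- readMetadata(cfg)
    dir.create(studyPath(cfg, "maps"), showWarnings = FALSE)
    for (id in meta$subject) {
        dwi <- as.array(RNifti::readNifti(
            studyPath(cfg, "dwi", paste0(id, "_dwi.nii.gz"))))
        fit <- fitTensor(array(dwi, dim(dwi)), scheme)
        maps <- computeScalarMaps(fit)
        writeScalarMaps(maps, studyPath(cfg, "maps", id))
    }
    invisible(studyPath(cfg, "maps"))
}

#' @rdname pipelineStages
#' @export
stageHistogram <- function(cfg) {
    meta <- readMetadata(cfg)
    lab <- as.array(RNifti::readNifti(studyPath(cfg, "dwi", "labels.nii.gz")))
    roi <- array(lab > 0.5, dim(lab))   # forebrain ROI: tracts + parenchyma
    hists <- list(); fits <- list()
    for (j in seq_len(nrow(meta))) {
        id <- meta$subject[j]
        maps <- readScalarMaps(studyPath(cfg, "maps", id))
        fa <- faMap(maps)[roi & mapMask(maps)]
        hists[[id]] <- buildHistogram(fa, id, meta$group[j])
        fits[[id]] <- fitBurr(hists[[id]])
    }
    hw <- data.frame(subject = meta$subject, group = meta$group,
        stringsAsFactors = FALSE)
    hm <- t(vapply(hists, binHeights, numeric(100L)))
    colnames(hm) <- sprintf("bin%03d", seq_len(100L))
    writeTable(cbind(hw, hm), studyPath(cfg, "histograms",
        "fa_histograms.csv"))
    writeTable(burrFitTable(fits), studyPath(cfg, "histograms",
        "burr_fits.csv"))
    shift <- compareGroups(fits, hists, descriptor = cfg$descriptor)
    avg <- shift$groupAverageHistograms
    writeTable(data.frame(group = rownames(avg), avg, check.names = FALSE),
        studyPath(cfg, "histograms", "group_average_histograms.csv"))
    gm <- vapply(shift$values, mean, 0)
    writeTable(data.frame(descriptor = shift$descriptor,
        group1 = names(gm)[1], mean1 = gm[1],
        group2 = names(gm)[2], mean2 = gm[2],
        t = shift$t, df = shift$df, p = shift$p.value),
        studyPath(cfg, "histograms", "histogram_shift.csv"))
    invisible(studyPath(cfg, "histograms"))
}

#' @rdname pipelineStages
#' @export
stageRegionalStats <- function(cfg) {
    meta <- readMetadata(cfg)
    regions <- utils::read.csv(studyPath(cfg, "regions.csv"),
        stringsAsFactors = FALSE)
    lab <- as.array(RNifti::readNifti(studyPath(cfg, "dwi", "labels.nii.gz")))
    lab <- array(as.integer(round(lab)), dim(lab))
    rows <- list()
    for (j in seq_len(nrow(meta))) {
        id <- meta$subject[j]
        maps <- readScalarMaps(studyPath(cfg, "maps", id))
        rm <- regionalMeans(maps, lab, regions$region)
        rm$subject <- id; rm$group <- meta$group[j]
        rows[[id]] <- rm
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    writeTable(tab[, c("subject", "group", "region", "metric", "value")],
        studyPath(cfg, "regional", "regional_metrics.csv"))
    cmp <- list()
    for (met in c("FA", "RD", "AD", "MD")) {
        sub <- tab[tab$metric == met, ]
        res <- do.call(rbind, lapply(regions$region, function(rg) {
            v <- sub[sub$region == rg, ]
            a <- v$value[v$group == cfg$groups[2]]   # treated first: t > 0
            b <- v$value[v$group == cfg$groups[1]]   # means higher in treated
            tt <- studentT(a, b)
            data.frame(metric = met, region = rg,
                meanTreated = mean(a), semTreated = sd(a) / sqrt(length(a)),
                meanVehicle = mean(b), semVehicle = sd(b) / sqrt(length(b)),
                t = tt$t, df = tt$df, p = tt$p.value)
        }))
        fdr <- bkyFdr(res$p, q = cfg$q)
        res$q <- fdr$qValues
        res$discovery <- fdr$discovery
        cmp[[met]] <- res
    }
    writeTable(do.call(rbind, cmp), studyPath(cfg, "regional",
        "regional_comparisons.csv"))
    invisible(studyPath(cfg, "regional"))
}

#' @rdname pipelineStages
#' @export
stageMBP <- function(cfg) {
    plate <- utils::read.csv(studyPath(cfg, "mbp", "plate.csv"),
        stringsAsFactors = FALSE)
    std <- plate[plate$type == "standard", ]
    blank <- plate$signal[plate$type == "blank"][1]
    model <- fitStandardCurve(
        data.frame(nominal = std$nominal, signal = std$signal), blank = blank)
    p <- plateParams(model)
    writeTable(data.frame(parameter = names(p), value = unname(p)),
        studyPath(cfg, "mbp", "standard_curve.csv"))
    writeTable(cbind(model@standards, lloq = lloq(model)),
        studyPath(cfg, "mbp", "standards_backcalc.csv"))
    smp <- plate[plate$type == "sample", ]
    quant <- quantifySamples(data.frame(id = smp$id, signal = smp$signal,
        dilution = smp$dilution), model)
    writeTable(quant, studyPath(cfg, "mbp", "sample_quant.csv"))

    dev <- utils::read.csv(studyPath(cfg, "mbp", "mbp_development.csv"),
        stringsAsFactors = FALSE)
    an <- twoWayAnovaTukey(data.frame(value = dev$MBP,
        treatment = dev$group, age = dev$PND))
    writeTable(an$anova, studyPath(cfg, "mbp", "mbp_anova.csv"))
    writeTable(an$tukey, studyPath(cfg, "mbp", "mbp_tukey.csv"))

    ihcMeta <- utils::read.csv(studyPath(cfg, "ihc", "ihc_metadata.csv"),
        stringsAsFactors = FALSE)
    ihcMeta$percent <- vapply(seq_len(nrow(ihcMeta)), function(j) {
        im <- readIHCImage(studyPath(cfg, "ihc",
            paste0(ihcMeta$file[j], ".tif")))
        mk <- readIHCMask(studyPath(cfg, "ihc",
            paste0(ihcMeta$file[j], "_mask.tif")))
        percentPositiveArea(im, mk, cfg$ihc$bgIntensity,
            cfg$ihc$threshold)$percentPositive
    }, 0)
    writeTable(ihcMeta[, c("subject", "group", "PND", "trueFraction",
        "percent")], studyPath(cfg, "ihc", "ihc_area.csv"))
    byDay <- do.call(rbind, lapply(sort(unique(ihcMeta$PND)), function(a) {
        v <- ihcMeta[ihcMeta$PND == a, ]
        tt <- studentT(v$percent[v$group == cfg$groups[2]],
                       v$percent[v$group == cfg$groups[1]])
        data.frame(PND = a,
            meanTreated = mean(v$percent[v$group == cfg$groups[2]]),
            meanVehicle = mean(v$percent[v$group == cfg$groups[1]]),
            t = tt$t, df = tt$df, p = tt$p.value)
    }))
    fdr <- bkyFdr(byDay$p, q = cfg$q)
    byDay$q <- fdr$qValues
    byDay$discovery <- fdr$discovery
    writeTable(byDay, studyPath(cfg, "ihc", "ihc_comparisons.csv"))
    anI <- twoWayAnovaTukey(data.frame(value = ihcMeta$percent,
        treatment = ihcMeta$group, age = ihcMeta$PND))
    writeTable(anI$anova, studyPath(cfg, "ihc", "ihc_anova.csv"))
    writeTable(anI$tukey, studyPath(cfg, "ihc", "ihc_tukey.csv"))
    invisible(studyPath(cfg, "mbp"))
}

#' @rdname pipelineStages
#' @export
stageCorrelate <- function(cfg) {
    fits <- utils::read.csv(studyPath(cfg, "histograms", "burr_fits.csv"),
        stringsAsFactors = FALSE)
    quant <- utils::read.csv(studyPath(cfg, "mbp", "sample_quant.csv"),
        stringsAsFactors = FALSE)
    # same-pup design: only subjects with both a DTI median and a plate
    # measurement enter (inner join)
    j <- merge(fits[fits$converged, c("subject", "group", cfg$descriptor)],
               quant[, c("id", "neat")], by.x = "subject", by.y = "id")
    res <- pearsonCorrelation(j$neat, j[[cfg$descriptor]])
    writeTable(data.frame(descriptor = cfg$descriptor, r = res$r,
        r_squared = res$r.squared, p = res$p.value, n = res$n),
        studyPath(cfg, "correlation.csv"))
    invisible(studyPath(cfg, "correlation.csv"))
}

#' @rdname pipelineStages
#' @export
stageReport <- function(cfg) {
    rd <- function(...) utils::read.csv(studyPath(cfg, ...),
        stringsAsFactors = FALSE)
    shift <- rd("histograms", "histogram_shift.csv")
    reg <- rd("regional", "regional_comparisons.csv")
    anova <- rd("mbp", "mbp_anova.csv")
    corr <- rd("correlation.csv")
    teeth <- rd("teeth.csv")
    ihc <- rd("ihc", "ihc_comparisons.csv")
    tab <- as.matrix(teeth[, c("erupted", "notErupted")])
    fisherP <- fisherExact2x2(tab)
    writeTable(data.frame(p = fisherP), studyPath(cfg, "fisher.csv"))

    fmt <- function(x, d = 4) formatC(x, digits = d, format = "g")
    lines <- c("# Synthetic myelination study report", "",
        "## Tooth eruption (Fisher's exact test)", "",
        sprintf("- %s: %d/%d erupted; %s: %d/%d erupted; two-sided p = %s",
            teeth$group[1], teeth$erupted[1],
            teeth$erupted[1] + teeth$notErupted[1],
            teeth$group[2], teeth$erupted[2],
            teeth$erupted[2] + teeth$notErupted[2], fmt(fisherP)), "",
        "## Regional white-matter comparisons (Student t, BKY FDR)", "",
        sprintf("- %s / %s: t = %s, p = %s, q = %s%s",
            reg$metric, reg$region, fmt(reg$t), fmt(reg$p), fmt(reg$q),
            ifelse(reg$discovery, " [discovery]", "")), "",
        "## Forebrain FA histogram shift (Burr fits, Welch t)", "",
        sprintf("- %s: %s mean %s vs %s mean %s; t = %s, df = %s, p = %s",
            shift$descriptor, shift$group1, fmt(shift$mean1),
            shift$group2, fmt(shift$mean2), fmt(shift$t), fmt(shift$df, 3),
            fmt(shift$p)), "",
        "## Developmental MBP (two-way ANOVA)", "",
        sprintf("- %s: F(%d, %d) = %s, p = %s", anova$term,
            anova$df1, anova$df2, fmt(anova$F), fmt(anova$p)), "",
        "## IHC percent positive area (per-day t, BKY FDR)", "",
        sprintf("- PND%d: treated %s%% vs vehicle %s%%, p = %s, q = %s%s",
            ihc$PND, fmt(ihc$meanTreated, 3), fmt(ihc$meanVehicle, 3),
            fmt(ihc$p), fmt(ihc$q), ifelse(ihc$discovery, " [discovery]", "")),
        "",
        "## MBP vs FA-median correlation (Pearson)", "",
        sprintf("- r = %s, r^2 = %s, p = %s, n = %d", fmt(corr$r),
            fmt(corr$r_squared), fmt(corr$p), corr$n), "",
        "## Provenance", "",
        sprintf("- seed: %d", cfg$seed),
        sprintf("- config md5: %s",
            unname(tools::md5sum(studyPath(cfg, "config.yaml")))),
        sprintf("- myelindex version: %s",
            as.character(utils::packageVersion("myelindex"))))
    writeLines(lines, studyPath(cfg, "report.md"))
    invisible(studyPath(cfg, "report.md"))
}

#' Run the full synthetic study
#'
#' Chains [pipelineStages] simulate, fit-dti, histogram, regional stats,
#' MBP/IHC, correlation and report. A stage failure aborts with the failing
#' stage named; artifacts written by earlier stages are retained. The run is
#' deterministic given the configuration seed.
#'
#' @param cfg a [studyConfig()] list.
#' @return a list of class `"studyReport"` with the main result tables
#'   (`histogramShift`, `regional`, `mbpAnova`, `ihcComparisons`,
#'   `correlation`, `fisherP`) and `outDir`.
#' @export
runFullStudy <- function(cfg) {
    stages <- list(simulate = stageSimulate, `fit-dti` = stageFitDTI,
        histogram = stageHistogram, `regional-stats` = stageRegionalStats,
        mbp = stageMBP, correlate = stageCorrelate, report = stageReport)
    for (nm in names(stages)) {
        res <- tryCatch(stages[[nm]](cfg), error = function(e)
            stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
                 call. = FALSE))
    }
    rd <- function(...) utils::read.csv(studyPath(cfg, ...),
        stringsAsFactors = FALSE)
    structure(list(
        histogramShift = rd("histograms", "histogram_shift.csv"),
        regional = rd("regional", "regional_comparisons.csv"),
        mbpAnova = rd("mbp", "mbp_anova.csv"),
        ihcComparisons = rd("ihc", "ihc_comparisons.csv"),
        correlation = rd("correlation.csv"),
        fisherP = rd("fisher.csv")$p,
        outDir = cfg$outDir), class = "studyReport")
}

#' @export
print.studyReport <- function(x, ...) {
    cat("Synthetic myelination study --", x$outDir, "\n")
    s <- x$histogramShift
    cat(sprintf("  FA shift (%s): %.4f vs %.4f, Welch p = %.4g\n",
        s$descriptor, s$mean1, s$mean2, s$p))
    cat(sprintf("  Regional discoveries: %d of %d tests\n",
        sum(x$regional$discovery), nrow(x$regional)))
    a <- x$mbpAnova
    cat(sprintf("  MBP ANOVA treatment: F(%d, %d) = %.4g, p = %.4g\n",
        a$df1[1], a$df2[1], a$F[1], a$p[1]))
    cat(sprintf("  MBP ~ FA median: r = %.3f (r^2 = %.3f), p = %.4g, n = %d\n",
        x$correlation$r, x$correlation$r_squared, x$correlation$p,
        x$correlation$n))
    cat(sprintf("  Teeth Fisher p = %.4g\n", x$fisherP))
    invisible(x)
}
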