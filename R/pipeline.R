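# recursive merge of user settings over defaults
mergeConfig <- function(user, defaults) {
    if (is.null(user)) return(defaults)
    for (k in names(defaults)) {
        if (is.null(user[[k]])) user[[k]] <- defaults[[k]]
        else if (is.list(defaults[[k]]) && is.list(user[[k]]))
            user[[k]] <- mergeConfig(user[[k]], defaults[[k]])
    }
    user
}

runConfigDefaults <- function() {
    list(label = "simpull-run", seed = 1L, nFields = 3L,
         simulation = list(),
         control = NULL,
         detect = list(projectionFrames = 10L, thresholdFactor = 5,
                       minSeparationPx = 3),
         steps = list(run = TRUE, maxSteps = 5L, penalty = 2,
                      minDwellFrames = 3L, apertureRadiusPx = 3,
                      annulusPx = c(5, 7)),
         stoichiometry = list(maturation = 0.75, nMax = 4L,
                              callThreshold = 0.1),
         colocalization = list(radiusPx = 2, registerOffset = TRUE),
         specificity = list(threshold = 5, epsilon = 0.5),
         writeImages = FALSE)
}

#' Read a pipeline run configuration from YAML
#'
#' A run configuration is a nested list: an experiment `label`, a `seed`,
#' `nFields` replicate imaging areas, a `simulation` block of
#' [SimulationConfig()] arguments, an optional `control` block (simulation
#' arguments for the antibody-control chamber, typically surface density 0
#' with only nonspecific binders), and parameter blocks `detect`, `steps`,
#' `stoichiometry`, `colocalization`, `specificity`. Missing entries take
#' package defaults; the fully resolved configuration is dumped into the run
#' report for provenance.
#'
#' @param path YAML file path.
#' @return the resolved run-configuration list.
#' @export
readRunConfig <- function(path) {
    mergeConfig(yaml::read_yaml(path), runConfigDefaults())
}

runConfigHash <- function(resolved) {
    tf <- tempfile(fileext = ".yaml")
    on.exit(unlink(tf))
    yaml::write_yaml(resolved, tf)
    unname(tools::md5sum(tf))
}

quantToList <- function(q) {
    list(counts = fieldCounts(q), mean = fieldMean(q),
         sd = fieldSD(q), nAreas = nAreas(q), channel = channelName(q),
         areaUm2 = q@areaUm2)
}

# spots safely inside the aperture+annulus margin of the field
traceableSpots <- function(spots, stack, annulusOuter = 7) {
    d <- dim(frames(stack))
    m <- ceiling(annulusOuter)
    ok <- round(spots$y_px) - m >= 1 & round(spots$y_px) + m <= d[1] &
          round(spots$x_px) - m >= 1 & round(spots$x_px) + m <= d[2]
    spots[ok, , drop = FALSE]
}

simulateFieldAt <- function(simArgs, runSeed, seedBase, i) {
    simArgs$seed <- childSeed(runSeed, seedBase + i)
    simulateField(do.call(SimulationConfig, simArgs))
}

#' Run the full SiMPull quantitation pipeline from one configuration
#'
#' Executes simulate -> detect -> quantify (+ control comparison) ->
#' traces -> step counting -> stoichiometry, and, for two-channel
#' configurations, registration and colocalization; writes intermediate
#' tables (spots, step fits, step distribution, colocalization per field)
#' plus a JSON report to `outDir`, and returns the [RunReport-class]. The
#' run is deterministic given the configuration seed: re-running the same
#' configuration reproduces the report bit-identically. Any stage failure
#' aborts with a stage-tagged error.
#'
#' @param config a run-configuration list (see [readRunConfig()]) or a path
#'   to its YAML file.
#' @param outDir output directory (created if needed); `NULL` for no files.
#' @return a [RunReport-class].
#' @examples
#' cfg <- list(label = "tiny", seed = 4, nFields = 2,
#'     simulation = list(fieldWidthPx = 64, fieldHeightPx = 64,
#'         nFrames = 12, surfaceDensity = 0.2, maturationProb = 1),
#'     steps = list(run = FALSE))
#' rep <- runPipeline(cfg)
#' @export
runPipeline <- function(config, outDir = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    cfg <- mergeConfig(config, runConfigDefaults())
    hash <- runConfigHash(cfg)
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage [", name, "] failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    stages <- list()
    flags <- character(0)

    # --- simulate / detect / trace, one field at a time ---------------------
    # stacks are large (a 5000 um^2 field at 400 frames is ~0.7 GB/channel),
    # so each field is simulated, measured and discarded before the next
    det <- cfg$detect
    st <- cfg$steps
    doSteps <- isTRUE(st$run)
    spotsByChannel <- list()
    fits <- list()
    moleculeEntries <- 0L
    nFluor <- 0L; nUnbleached <- 0L
    simCfg <- NULL; channels <- NULL
    for (i in seq_len(cfg$nFields)) {
        fld <- stage("simulate",
                     simulateFieldAt(cfg$simulation, cfg$seed, 0L, i))
        if (i == 1L) {
            simCfg <- fld@config
            channels <- names(stacks(fld))
        }
        fl <- truth(fld)@fluorophores
        moleculeEntries <- moleculeEntries + nrow(truth(fld)@molecules)
        nFluor <- nFluor + nrow(fl)
        nUnbleached <- nUnbleached + sum(fl$bleach_frame > simCfg@nFrames)
        if (!is.null(outDir) && isTRUE(cfg$writeImages)) stage("simulate", {
            for (ch in channels)
                writeImageStack(stacks(fld)[[ch]], file.path(outDir,
                    sprintf("field%02d_channel%s.tif", i, ch)))
            writeGroundTruth(truth(fld), file.path(outDir,
                sprintf("ground_truth_field%02d.csv", i)))
        })
        fieldSpots <- stage("detect", lapply(channels, function(ch)
            detectSpots(stacks(fld)[[ch]],
                projectionFrames = det$projectionFrames,
                thresholdFactor = det$thresholdFactor,
                minSeparationPx = det$minSeparationPx, field = i)))
        names(fieldSpots) <- channels
        for (ch in channels)
            spotsByChannel[[ch]] <- rbind(spotsByChannel[[ch]],
                                          fieldSpots[[ch]])
        if (doSteps) {
            stkA <- stacks(fld)$A
            sp <- traceableSpots(fieldSpots$A, stkA, st$annulusPx[2])
            fits <- c(fits, stage("steps", lapply(seq_len(nrow(sp)),
                function(j) {
                    tr <- extractTrace(stkA, sp[j, ],
                                       apertureRadiusPx = st$apertureRadiusPx,
                                       annulusPx = st$annulusPx)
                    countSteps(tr, maxSteps = st$maxSteps,
                               penalty = st$penalty,
                               minDwellFrames = st$minDwellFrames)
                })))
        }
        rm(fld)
    }
    areaUm2 <- fieldAreaUm2(simCfg)
    stages$simulate <- list(nFields = cfg$nFields, areaUm2 = areaUm2,
        nChannels = length(channels), moleculeEntries = moleculeEntries,
        fractionUnbleached = if (nFluor) nUnbleached / nFluor else NA_real_)

    # --- quantify -----------------------------------------------------------
    quants <- stage("detect", lapply(channels, function(ch) {
        sp <- spotsByChannel[[ch]]
        tabs <- lapply(seq_len(cfg$nFields), function(i)
            sp[sp$field == i, , drop = FALSE])
        quantifyFields(tabs, fieldAreaUm2 = areaUm2, channel = ch)
    }))
    names(quants) <- channels
    stages$detect <- lapply(quants, quantToList)
    if (all(vapply(quants, fieldMean, numeric(1)) == 0))
        flags <- c(flags, "no spots detected in any channel")
    if (!is.null(outDir))
        writeSpots(do.call(rbind, spotsByChannel),
                   file.path(outDir, "spots.csv"))

    # --- control comparison -------------------------------------------------
    if (!is.null(cfg$control)) {
        ctrlArgs <- mergeConfig(cfg$control, cfg$simulation)
        ctrlTabs <- stage("control", lapply(seq_len(cfg$nFields),
            function(i) {
                fld <- simulateFieldAt(ctrlArgs, cfg$seed, 1000L, i)
                detectSpots(stacks(fld)$A,
                    projectionFrames = det$projectionFrames,
                    thresholdFactor = det$thresholdFactor,
                    minSeparationPx = det$minSeparationPx, field = i)
            }))
        ctrlQuant <- quantifyFields(ctrlTabs, fieldAreaUm2 = areaUm2,
                                    channel = "A")
        cmp <- compareToControl(quants[[1]], ctrlQuant,
                                threshold = cfg$specificity$threshold,
                                epsilon = cfg$specificity$epsilon)
        stages$specificity <- c(cmp, list(control = quantToList(ctrlQuant)))
    }

    # --- step distribution + stoichiometry ----------------------------------
    if (doSteps) {
        if (length(fits)) {
            dist <- buildStepDistribution(fits)
            stages$steps <- list(counts = as.list(stepCounts(dist)),
                                 rejected = as.list(dist@rejected),
                                 nTraces = length(fits))
            if (sum(stepCounts(dist)) > 0) {
                sto <- cfg$stoichiometry
                est <- stage("stoichiometry", inferStoichiometry(dist,
                    m = sto$maturation, nMax = sto$nMax,
                    callThreshold = sto$callThreshold))
                raw <- stage("stoichiometry", inferStoichiometry(dist,
                    m = 1, nMax = sto$nMax,
                    callThreshold = sto$callThreshold))
                stages$stoichiometry <- list(
                    maturation = sto$maturation,
                    weights = as.list(mixtureWeights(est)),
                    call = dominantSpecies(est),
                    logLik = est@logLik,
                    predicted = as.list(est@predicted),
                    observed = as.list(est@observed),
                    rawWeights = as.list(mixtureWeights(raw)),
                    rawCall = dominantSpecies(raw))
            } else flags <- c(flags, "no accepted traces: stoichiometry skipped")
            if (!is.null(outDir)) {
                df <- data.frame(
                    trace = seq_along(fits),
                    n_steps = vapply(fits, nSteps, integer(1)),
                    accepted = vapply(fits, isAccepted, logical(1)),
                    reason = vapply(fits, function(f) f@reason, character(1)),
                    rss = vapply(fits, function(f) f@rss, numeric(1)))
                utils::write.csv(df, file.path(outDir, "step_fits.csv"),
                                 row.names = FALSE)
            }
        } else {
            flags <- c(flags, "no traceable spots: step analysis skipped")
            stages$steps <- list(counts = list(), rejected = list(),
                                 nTraces = 0L)
        }
    }

    # --- colocalization -----------------------------------------------------
    if (length(channels) == 2L) {
        col <- cfg$colocalization
        spotsB <- spotsByChannel$B
        if (isTRUE(col$registerOffset))
            spotsB <- registerChannels(spotsB, simCfg@channelOffsetPx)
        res <- stage("colocalize", colocalize(spotsByChannel$A, spotsB,
            radiusPx = col$radiusPx,
            fieldAreaPx2 = simCfg@fieldWidthPx * simCfg@fieldHeightPx))
        stages$colocalization <- list(meanPct = colocalizationPct(res),
            sdPct = res@sdPct, expectedChancePct = res@expectedChancePct,
            radiusPx = res@radiusPx, flags = res@flags,
            perField = perFieldStats(res))
        flags <- c(flags, res@flags)
        if (!is.null(outDir))
            utils::write.csv(perFieldStats(res),
                             file.path(outDir, "colocalization.csv"),
                             row.names = FALSE)
    }

    stages$flags <- flags
    report <- new("RunReport", label = cfg$label,
                  seed = as.integer(cfg$seed), configHash = hash,
                  version = as.character(utils::packageVersion("SiMPullCount")),
                  stages = c(stages, list(config = cfg)))
    if (!is.null(outDir))
        writeRunReport(report, file.path(outDir, "report.json"))
    report
}

#' Write a run report as JSON
#'
#' @param report a [RunReport-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeRunReport <- function(report, path) {
    jsonlite::write_json(list(label = report@label, seed = report@seed,
        configHash = report@configHash, version = report@version,
        stages = report@stages), path, auto_unbox = TRUE, digits = NA,
        pretty = TRUE, null = "null")
    invisible(path)
}
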