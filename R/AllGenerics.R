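#' @include AllClasses.R
NULL

#' Accessors for SiMPullCount classes
#'
#' Small accessor family: `frames()` returns the pixel array of an
#' [ImageStack-class]; `channelName()` its channel label; `truth()` and
#' `stacks()` unpack a [SimPullField-class]; `fieldCounts()`, `fieldMean()`,
#' `fieldSD()` and `nAreas()` summarize a [FieldQuantification-class];
#' `traceValues()` returns the per-frame intensities of an
#' [IntensityTrace-class]; `nSteps()`, `stepFrames()`, `stepSizes()` and
#' `isAccepted()` read a [StepFit-class]; `stepCounts()` the histogram of a
#' [StepDistribution-class]; `mixtureWeights()` and `dominantSpecies()` a
#' [StoichiometryEstimate-class]; `colocalizationPct()` and `perFieldStats()`
#' a [ColocalizationResult-class].
#'
#' @param x the object.
#' @return the slot value described above.
#' @name accessors
#' @aliases frames channelName truth stacks fieldCounts fieldMean fieldSD
#'   nAreas traceValues nSteps stepFrames stepSizes isAccepted stepCounts
#'   mixtureWeights dominantSpecies colocalizationPct perFieldStats
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))
#' @rdname accessors
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))
#' @rdname accessors
#' @export
setGeneric("stacks", function(x) standardGeneric("stacks"))
#' @rdname accessors
#' @export
setGeneric("fieldCounts", function(x) standardGeneric("fieldCounts"))
#' @rdname accessors
#' @export
setGeneric("fieldMean", function(x) standardGeneric("fieldMean"))
#' @rdname accessors
#' @export
setGeneric("fieldSD", function(x) standardGeneric("fieldSD"))
#' @rdname accessors
#' @export
setGeneric("nAreas", function(x) standardGeneric("nAreas"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))
#' @rdname accessors
#' @export
setGeneric("stepFrames", function(x) standardGeneric("stepFrames"))
#' @rdname accessors
#' @export
setGeneric("stepSizes", function(x) standardGeneric("stepSizes"))
#' @rdname accessors
#' @export
setGeneric("isAccepted", function(x) standardGeneric("isAccepted"))
#' @rdname accessors
#' @export
setGeneric("stepCounts", function(x) standardGeneric("stepCounts"))
#' @rdname accessors
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))
#' @rdname accessors
#' @export
setGeneric("dominantSpecies", function(x) standardGeneric("dominantSpecies"))
#' @rdname accessors
#' @export
setGeneric("colocalizationPct", function(x) standardGeneric("colocalizationPct"))
#' @rdname accessors
#' @export
setGeneric("perFieldStats", function(x) standardGeneric("perFieldStats"))

#' @rdname accessors
setMethod("frames", "ImageStack", function(x) x@frames)
#' @rdname accessors
setMethod("channelName", "ImageStack", function(x) x@channel)
#' @rdname accessors
setMethod("truth", "SimPullField", function(x) x@truth)
#' @rdname accessors
setMethod("stacks", "SimPullField", function(x) x@stacks)
#' @rdname accessors
setMethod("fieldCounts", "FieldQuantification", function(x) x@counts)
#' @rdname accessors
setMethod("fieldMean", "FieldQuantification", function(x) mean(x@counts))
#' @rdname accessors
setMethod("fieldSD", "FieldQuantification", function(x)
    if (length(x@counts) > 1L) stats::sd(x@counts) else NA_real_)
#' @rdname accessors
setMethod("nAreas", "FieldQuantification", function(x) length(x@counts))
#' @rdname accessors
setMethod("channelName", "FieldQuantification", function(x) x@channel)
#' @rdname accessors
setMethod("traceValues", "IntensityTrace", function(x) x@values)
#' @rdname accessors
setMethod("nSteps", "StepFit", function(x) x@nSteps)
#' @rdname accessors
setMethod("stepFrames", "StepFit", function(x) x@stepFrames)
#' @rdname accessors
setMethod("stepSizes", "StepFit", function(x) x@stepSizes)
#' @rdname accessors
setMethod("isAccepted", "StepFit", function(x) x@accepted)
#' @rdname accessors
setMethod("stepCounts", "StepDistribution", function(x) x@counts)
#' @rdname accessors
setMethod("mixtureWeights", "StoichiometryEstimate", function(x) x@weights)
#' @rdname accessors
setMethod("dominantSpecies", "StoichiometryEstimate", function(x) x@call)
#' @rdname accessors
setMethod("colocalizationPct", "ColocalizationResult", function(x) x@meanPct)
#' @rdname accessors
setMethod("perFieldStats", "ColocalizationResult", function(x) x@perField)

setMethod("show", "SimulationConfig", function(object) {
    areaUm2 <- object@fieldWidthPx * object@fieldHeightPx *
        (object@pixelSizeNm / 1000)^2
    cat("SimulationConfig:", object@fieldWidthPx, "x", object@fieldHeightPx,
        "px (", format(round(areaUm2, 1)), "um^2 ),",
        object@nFrames, "frames,", object@nChannels, "channel(s)\n")
    cat("  density", object@surfaceDensity, "/um^2; maturation",
        paste(object@maturationProb, collapse = "/"),
        "; bleach/frame", object@bleachProbPerFrame, "\n")
    if (object@nChannels == 2L)
        cat("  co-complex fraction", object@coComplexFraction,
            "; partner-only density", object@partnerOnlyDensity, "/um^2\n")
})

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@frames)
    cat("ImageStack channel", object@channel, ":", d[1], "x", d[2],
        "px,", d[3], "frames,", object@pixelSizeNm, "nm/px\n")
})

setMethod("show", "SimPullField", function(object) {
    cat("SimPullField with", length(object@stacks), "channel(s),",
        nrow(object@truth@molecules), "ground-truth molecule entries\n")
})

setMethod("show", "FieldQuantification", function(object) {
    cat(sprintf(
        "FieldQuantification [%s]: %.1f +/- %.1f molecules per %g um^2 (n = %d areas)\n",
        object@channel, mean(object@counts),
        if (length(object@counts) > 1) stats::sd(object@counts) else NA_real_,
        object@areaUm2, length(object@counts)))
})

setMethod("show", "StepFit", function(object) {
    cat("StepFit:", object@nSteps, "step(s)",
        if (object@nSteps) paste0("at frame(s) ",
            paste(object@stepFrames, collapse = ", ")) else "",
        "| accepted:", object@accepted,
        if (!object@accepted) paste0(" (", object@reason, ")") else "", "\n")
})

setMethod("show", "StepDistribution", function(object) {
    cat("StepDistribution:", sum(object@counts), "accepted,",
        sum(object@rejected), "rejected\n")
    if (length(object@counts)) {
        tab <- object@counts
        cat("  steps:", paste(sprintf("%s:%d", names(tab), tab),
                              collapse = "  "), "\n")
    }
    if (any(object@rejected > 0)) {
        rej <- object@rejected[object@rejected > 0]
        cat("  rejected:", paste(sprintf("%s:%d", names(rej), rej),
                                 collapse = "  "), "\n")
    }
})

setMethod("show", "StoichiometryEstimate", function(object) {
    cat("StoichiometryEstimate (maturation =", object@maturation, "):\n")
    w <- round(object@weights, 3)
    cat("  weights:", paste(sprintf("n=%s:%.3f", names(w), w),
                            collapse = "  "), "\n")
    cat("  call:", object@call, "| logLik:", round(object@logLik, 2), "\n")
})

setMethod("show", "ColocalizationResult", function(object) {
    cat(sprintf(
        "ColocalizationResult: %.1f +/- %.1f %% (radius %g px, %d field(s))\n",
        object@meanPct, object@sdPct, object@radiusPx, nrow(object@perField)))
    if (!is.na(object@expectedChancePct))
        cat(sprintf("  expected chance colocalization: %.2f %%\n",
                    object@expectedChancePct))
    if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "RunReport", function(object) {
    cat("RunReport '", object@label, "' (seed ", object@seed, ", config ",
        substr(object@configHash, 1, 8), ")\n", sep = "")
    cat("  stages:", paste(names(object@stages), collapse = ", "), "\n")
})
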