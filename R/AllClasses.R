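#' @import methods
NULL

#' Generative parameters for a synthetic SiMPull field
#'
#' `SimulationConfig` holds every parameter of the synthetic TIRF-field
#' generator: field geometry, optics, surface densities, labeling
#' (copy-number distribution and chromophore maturation), photobleaching
#' kinetics, camera noise, and the two-channel co-complex structure.
#'
#' The default geometry is one imaging area of about 5000 um^2 (471 x 471
#' pixels at 150 nm/pixel, so that a 2-pixel distance corresponds to the
#' ~300 nm diffraction limit). Photobleaching is memoryless: each active
#' fluorophore survives a frame with probability `1 - bleachProbPerFrame`,
#' giving exponential bleaching kinetics.
#'
#' For two-channel fields, every specific complex carries a channel-A label;
#' a fraction `coComplexFraction` additionally carries a channel-B partner at
#' the same surface position, and an independent population of B-only
#' complexes is laid down at `partnerOnlyDensity` (emulating the partner
#' protein being pulled down in excess, so that channel A is the
#' lower-density channel used as the colocalization denominator).
#'
#' @slot fieldWidthPx,fieldHeightPx integer field size in pixels.
#' @slot pixelSizeNm numeric, nm per pixel.
#' @slot nFrames integer number of movie frames.
#' @slot psfSigmaPx numeric Gaussian PSF sigma in pixels.
#' @slot surfaceDensity numeric, specific complexes per um^2.
#' @slot copyNumberDist list of per-channel probability vectors over subunit
#'   copy numbers 1..n_max (a single vector is recycled to both channels).
#' @slot maturationProb numeric per-channel probability that a fluorophore
#'   has matured into an active chromophore.
#' @slot bleachProbPerFrame numeric per-frame bleaching probability.
#' @slot unitIntensity numeric photons/frame emitted by one active fluorophore.
#' @slot backgroundLevel numeric photons/frame/pixel background.
#' @slot readNoiseSd numeric Gaussian read noise (photons).
#' @slot coComplexFraction numeric probability that a channel-A complex
#'   carries a channel-B partner.
#' @slot partnerOnlyDensity numeric, channel-B-only complexes per um^2.
#' @slot channelOffsetPx numeric length-2 (x, y) misregistration of channel B.
#' @slot nonspecificDensity numeric, nonspecific monomeric binders per um^2
#'   (per channel).
#' @slot nChannels integer, 1 or 2.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
    representation(
        fieldWidthPx = "integer", fieldHeightPx = "integer",
        pixelSizeNm = "numeric", nFrames = "integer",
        psfSigmaPx = "numeric", surfaceDensity = "numeric",
        copyNumberDist = "list", maturationProb = "numeric",
        bleachProbPerFrame = "numeric", unitIntensity = "numeric",
        backgroundLevel = "numeric", readNoiseSd = "numeric",
        coComplexFraction = "numeric", partnerOnlyDensity = "numeric",
        channelOffsetPx = "numeric", nonspecificDensity = "numeric",
        nChannels = "integer", seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    probs <- c(object@maturationProb, object@bleachProbPerFrame,
               object@coComplexFraction)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "all probabilities must lie in [0, 1]")
    if (object@fieldWidthPx < 1L || object@fieldHeightPx < 1L)
        msg <- c(msg, "field dimensions must be positive")
    if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
    if (object@pixelSizeNm <= 0) msg <- c(msg, "pixelSizeNm must be > 0")
    nonneg <- c(object@psfSigmaPx, object@surfaceDensity,
                object@partnerOnlyDensity, object@unitIntensity,
                object@backgroundLevel, object@readNoiseSd,
                object@nonspecificDensity)
    if (any(nonneg < 0))
        msg <- c(msg, "densities, intensities, sigmas must be >= 0")
    if (!object@nChannels %in% c(1L, 2L))
        msg <- c(msg, "nChannels must be 1 or 2")
    if (length(object@channelOffsetPx) != 2L)
        msg <- c(msg, "channelOffsetPx must have length 2")
    for (p in object@copyNumberDist) {
        if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
            msg <- c(msg, "each copyNumberDist must be a probability vector summing to 1")
    }
    if (length(msg)) msg else TRUE
})

#' Per-molecule ground truth for a simulated field
#'
#' Two tables: `molecules` has one row per (molecule, channel) entry with the
#' true subpixel position (in channel-A coordinates, before any channel
#' offset), true and matured (fluorescent) copy numbers, and the nonspecific
#' and co-complex flags; `fluorophores` has one row per matured fluorophore
#' with its bleach frame (the first dark frame).
#'
#' @slot molecules data.frame with columns `molecule`, `channel`, `x_px`,
#'   `y_px`, `copies`, `fluorescent`, `is_nonspecific`, `is_co_complex`.
#' @slot fluorophores data.frame with columns `molecule`, `channel`,
#'   `bleach_frame`.
#' @export
setClass("GroundTruth",
    representation(molecules = "data.frame", fluorophores = "data.frame"))

setValidity("GroundTruth", function(object) {
    m <- object@molecules
    msg <- character()
    if (nrow(m)) {
        if (any(m$fluorescent > m$copies))
            msg <- c(msg, "fluorescent copies must not exceed true copies")
        cc <- m[m$is_co_complex, , drop = FALSE]
        if (nrow(cc)) {
            byMol <- split(cc, cc$molecule)
            both <- vapply(byMol, function(d)
                all(c("A", "B") %in% d$channel) &&
                    length(unique(d$x_px)) == 1L &&
                    length(unique(d$y_px)) == 1L, logical(1))
            if (!all(both))
                msg <- c(msg, "co-complex molecules need identical entries in both channels")
        }
    }
    if (length(msg)) msg else TRUE
})

#' A single-channel TIRF movie
#'
#' A time series of 2-D photon-count frames for one channel of one field of
#' view, stored as a `(row, column, frame)` array.
#'
#' @slot frames numeric 3-D array `(row, col, frame)` of nonnegative photon
#'   counts.
#' @slot channel character channel label (e.g. "A", "B").
#' @slot pixelSizeNm numeric nm per pixel.
#' @export
setClass("ImageStack",
    representation(frames = "array", channel = "character",
                   pixelSizeNm = "numeric"))

setValidity("ImageStack", function(object) {
    d <- dim(object@frames)
    if (length(d) != 3L) return("frames must be a 3-D array (row, col, frame)")
    # min() avoids materializing a full-size logical mask on large stacks
    if (length(object@frames) && min(object@frames) < 0)
        return("pixel values must be >= 0")
    if (object@pixelSizeNm <= 0) return("pixelSizeNm must be > 0")
    TRUE
})

#' A simulated SiMPull field: image stacks plus ground truth
#'
#' @slot stacks list of [ImageStack-class], one per channel, named "A" (and
#'   "B" for two-channel fields).
#' @slot truth a [GroundTruth-class].
#' @slot config the generating [SimulationConfig-class].
#' @export
setClass("SimPullField",
    representation(stacks = "list", truth = "GroundTruth",
                   config = "SimulationConfig"))

#' Molecule counts per imaging area
#'
#' Counts of detected molecules per replicate imaging area, rescaled to the
#' reference area (5000 um^2 by default). The mean is the arithmetic mean of
#' the per-area counts and the s.d. uses the n - 1 denominator.
#'
#' @slot counts numeric per-area molecule counts (per `areaUm2`).
#' @slot channel character channel label.
#' @slot areaUm2 numeric reference imaging area in um^2.
#' @export
setClass("FieldQuantification",
    representation(counts = "numeric", channel = "character",
                   areaUm2 = "numeric"))

setValidity("FieldQuantification", function(object) {
    if (length(object@counts) < 1L) return("at least one imaging area required")
    if (any(object@counts < 0)) return("counts must be >= 0")
    TRUE
})

#' Background-corrected intensity trajectory of one spot
#'
#' @slot values numeric per-frame background-corrected integrated intensity
#'   (photons).
#' @slot apertureRadiusPx numeric aperture radius (pixels).
#' @slot annulusPx numeric length-2 inner/outer background annulus radii.
#' @slot spot list with the source spot's position/channel/field (may be
#'   empty for simulated traces).
#' @slot meta list of extra metadata; simulated traces record their true
#'   step frames here.
#' @export
setClass("IntensityTrace",
    representation(values = "numeric", apertureRadiusPx = "numeric",
                   annulusPx = "numeric", spot = "list", meta = "list"))

#' Fitted photobleaching staircase for one trace
#'
#' @slot nSteps integer number of retained steps.
#' @slot stepFrames integer frames at which the level changes (last frame of
#'   the previous plateau), strictly increasing.
#' @slot stepSizes numeric signed step sizes (photons); bleaching steps are
#'   negative.
#' @slot plateaus numeric plateau levels (length `nSteps + 1`).
#' @slot rss numeric residual sum of squares of the staircase fit.
#' @slot noiseSd numeric robust per-frame noise s.d. estimate.
#' @slot accepted logical whether the trace enters the step distribution.
#' @slot reason character one of "none", "no_full_bleach", "too_many_steps",
#'   "upward_step", "low_snr".
#' @export
setClass("StepFit",
    representation(nSteps = "integer", stepFrames = "integer",
                   stepSizes = "numeric", plateaus = "numeric",
                   rss = "numeric", noiseSd = "numeric",
                   accepted = "logical", reason = "character"))

setValidity("StepFit", function(object) {
    if (object@nSteps != length(object@stepFrames))
        return("nSteps must equal length(stepFrames)")
    if (is.unsorted(object@stepFrames, strictly = TRUE))
        return("step frames must be strictly increasing")
    if (length(object@plateaus) != object@nSteps + 1L)
        return("plateaus must have length nSteps + 1")
    TRUE
})

#' Population histogram of photobleaching step counts
#'
#' @slot counts named integer vector, names are step counts ("1", "2", ...),
#'   values the number of accepted traces with that count.
#' @slot rejected named integer vector of rejected-trace tallies by reason.
#' @export
setClass("StepDistribution",
    representation(counts = "integer", rejected = "integer"))

#' Inferred subunit copy-number mixture
#'
#' Maximum-likelihood mixture over copy numbers n = 1..nMax fitted to an
#' observed photobleaching step histogram under the binomial visible-step
#' model with chromophore maturation probability m.
#'
#' @slot weights named numeric mixture weights over n = 1..nMax (sum to 1).
#' @slot maturation numeric maturation probability used.
#' @slot logLik numeric maximized log-likelihood.
#' @slot predicted named numeric predicted step distribution (probabilities
#'   over observed steps j >= 1, sums to 1).
#' @slot observed named numeric the observed step histogram (counts).
#' @slot call character dominant-species call, e.g. "monomer" or
#'   "monomer + dimer".
#' @export
setClass("StoichiometryEstimate",
    representation(weights = "numeric", maturation = "numeric",
                   logLik = "numeric", predicted = "numeric",
                   observed = "numeric", call = "character"))

setValidity("StoichiometryEstimate", function(object) {
    if (any(object@weights < -1e-9) || abs(sum(object@weights) - 1) > 1e-6)
        return("mixture weights must be nonnegative and sum to 1")
    if (abs(sum(object@predicted) - 1) > 1e-6)
        return("predicted step distribution must sum to 1")
    TRUE
})

#' Two-channel colocalization summary
#'
#' Per-field spot counts, matched-pair counts and colocalization percentages
#' with the lower-density-channel denominator, plus the across-field mean,
#' s.d. and the chance-colocalization expectation.
#'
#' @slot perField data.frame with columns `field`, `nA`, `nB`,
#'   `refChannel`, `nRef`, `matched`, `pct`.
#' @slot radiusPx numeric match radius in pixels.
#' @slot meanPct,sdPct numeric across-field mean and s.d. (n - 1) of the
#'   percentage.
#' @slot expectedChancePct numeric chance colocalization percentage from the
#'   denser channel's density (NA if field geometry unknown).
#' @slot flags character vector of warnings (e.g. empty channels).
#' @export
setClass("ColocalizationResult",
    representation(perField = "data.frame", radiusPx = "numeric",
                   meanPct = "numeric", sdPct = "numeric",
                   expectedChancePct = "numeric", flags = "character"))

setValidity("ColocalizationResult", function(object) {
    pf <- object@perField
    if (nrow(pf)) {
        if (any(pf$pct < 0 | pf$pct > 100))
            return("percentages must lie in [0, 100]")
        if (any(pf$matched > pmin(pf$nA, pf$nB)))
            return("matched pairs cannot exceed min(nA, nB)")
    }
    TRUE
})

#' Reproducible end-to-end run report
#'
#' @slot label character experiment label.
#' @slot seed integer seed used for the run.
#' @slot configHash character md5 of the canonical config dump.
#' @slot version character package version.
#' @slot stages list of per-stage summaries.
#' @export
setClass("RunReport",
    representation(label = "character", seed = "integer",
                   configHash = "character", version = "character",
                   stages = "list"))
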