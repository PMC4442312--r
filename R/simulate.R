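#' Construct a simulation configuration
#'
#' Builds a [SimulationConfig-class] with defaults matching the assay's
#' standard regime: one imaging area of ~5000 um^2 (471 x 471 px at
#' 150 nm/px, so a 2-px distance is the ~300 nm diffraction limit), a
#' 400-frame movie, PSF sigma 1 px, ~100 specific complexes per area
#' (0.02 /um^2), monomeric labels, maturation probability 0.75 (a
#' conventional YFP-class estimate), geometric photobleaching at 0.01/frame,
#' 100 photons/frame per active fluorophore over a 10 photon background with
#' 2 photons read noise, and a nonspecific background of 0.002 /um^2.
#'
#' @param fieldWidthPx,fieldHeightPx field size in pixels.
#' @param pixelSizeNm nm per pixel.
#' @param nFrames number of frames.
#' @param psfSigmaPx Gaussian PSF sigma (pixels).
#' @param surfaceDensity specific complexes per um^2.
#' @param copyNumberDist probability vector over copies 1..n_max, or a list
#'   of two such vectors (channels A and B).
#' @param maturationProb per-channel maturation probability (length 1 or 2).
#' @param bleachProbPerFrame per-frame bleaching probability per fluorophore.
#' @param unitIntensity photons/frame per active fluorophore.
#' @param backgroundLevel photons/frame/pixel.
#' @param readNoiseSd Gaussian read noise s.d. (photons).
#' @param coComplexFraction probability a channel-A complex carries a
#'   channel-B partner (two-channel fields).
#' @param partnerOnlyDensity channel-B-only complexes per um^2.
#' @param channelOffsetPx length-2 (x, y) channel-B misregistration.
#' @param nonspecificDensity nonspecific monomeric binders per um^2 per
#'   channel.
#' @param nChannels 1 or 2.
#' @param seed integer RNG seed for [simulateField()].
#' @return a [SimulationConfig-class].
#' @examples
#' cfg <- SimulationConfig(surfaceDensity = 0.02, seed = 7)
#' cfg
#' @export
SimulationConfig <- function(fieldWidthPx = 471L, fieldHeightPx = 471L,
                             pixelSizeNm = 150, nFrames = 400L,
                             psfSigmaPx = 1.0, surfaceDensity = 0.02,
                             copyNumberDist = c(1),
                             maturationProb = 0.75,
                             bleachProbPerFrame = 0.01,
                             unitIntensity = 100, backgroundLevel = 10,
                             readNoiseSd = 2, coComplexFraction = 0,
                             partnerOnlyDensity = surfaceDensity,
                             channelOffsetPx = c(0, 0),
                             nonspecificDensity = 0.002,
                             nChannels = 1L, seed = 1L) {
    if (!is.list(copyNumberDist)) copyNumberDist <- list(copyNumberDist)
    if (length(copyNumberDist) == 1L && nChannels == 2L)
        copyNumberDist <- rep(copyNumberDist, 2L)
    maturationProb <- rep_len(maturationProb, as.integer(nChannels))
    new("SimulationConfig",
        fieldWidthPx = as.integer(fieldWidthPx),
        fieldHeightPx = as.integer(fieldHeightPx),
        pixelSizeNm = pixelSizeNm, nFrames = as.integer(nFrames),
        psfSigmaPx = psfSigmaPx, surfaceDensity = surfaceDensity,
        copyNumberDist = copyNumberDist, maturationProb = maturationProb,
        bleachProbPerFrame = bleachProbPerFrame,
        unitIntensity = unitIntensity, backgroundLevel = backgroundLevel,
        readNoiseSd = readNoiseSd, coComplexFraction = coComplexFraction,
        partnerOnlyDensity = partnerOnlyDensity,
        channelOffsetPx = as.numeric(channelOffsetPx),
        nonspecificDensity = nonspecificDensity,
        nChannels = as.integer(nChannels), seed = as.integer(seed))
}

#' Imaging area of a configured field, in um^2
#' @param config a [SimulationConfig-class].
#' @return numeric area in um^2.
#' @export
fieldAreaUm2 <- function(config) {
    config@fieldWidthPx * config@fieldHeightPx * (config@pixelSizeNm / 1000)^2
}

# pixel-integrated 2-D Gaussian PSF patch around subpixel center (x, y);
# returns list(rows, cols, patch) clipped to the field; patch sums to ~1
psfPatch <- function(x, y, sigma, W, H, radius = NULL) {
    if (is.null(radius)) radius <- max(3L, ceiling(5 * sigma))
    r0 <- max(1L, floor(y) - radius); r1 <- min(H, floor(y) + radius)
    c0 <- max(1L, floor(x) - radius); c1 <- min(W, floor(x) + radius)
    rows <- r0:r1; cols <- c0:c1
    py <- stats::pnorm(rows + 0.5, y, sigma) - stats::pnorm(rows - 0.5, y, sigma)
    px <- stats::pnorm(cols + 0.5, x, sigma) - stats::pnorm(cols - 0.5, x, sigma)
    list(rows = rows, cols = cols, patch = outer(py, px))
}

# add fluorophores (data.frame x, y, last_frame) to a signal array in place
renderFluorophores <- function(signal, fl, config) {
    if (!nrow(fl)) return(signal)
    d <- dim(signal); H <- d[1]; W <- d[2]; T <- d[3]
    for (i in seq_len(nrow(fl))) {
        lf <- min(fl$last_frame[i], T)
        if (lf < 1) next
        pp <- psfPatch(fl$x[i], fl$y[i], config@psfSigmaPx, W, H)
        if (!length(pp$rows) || !length(pp$cols)) next
        contrib <- outer(pp$patch * config@unitIntensity, rep(1, lf))
        signal[pp$rows, pp$cols, seq_len(lf)] <-
            signal[pp$rows, pp$cols, seq_len(lf), drop = FALSE] + contrib
    }
    signal
}

# geometric emission lengths (last emitting frame); Inf if bleaching is off
drawEmissionLengths <- function(n, p) {
    if (n == 0L) return(numeric())
    if (p <= 0) return(rep(Inf, n))
    stats::rgeom(n, p) + 1
}

#' Simulate a SiMPull field of view with ground truth
#'
#' Generates one synthetic TIRF field per the configuration: specific
#' complexes are laid down as a spatial Poisson process, each labeled subunit
#' matures into an active chromophore with the channel's maturation
#' probability, every active fluorophore emits `unitIntensity` photons/frame
#' spread by a pixel-integrated Gaussian PSF until its geometric bleach
#' frame, and pixel values are Poisson(signal + background) plus Gaussian
#' read noise, clipped at zero. For two-channel configurations, channel-B
#' positions are shifted by `channelOffsetPx`, a fraction
#' `coComplexFraction` of channel-A complexes carry a channel-B partner at
#' the same surface position, and an independent population of B-only
#' complexes is added at `partnerOnlyDensity`. Nonspecific monomeric binders
#' are added per channel at `nonspecificDensity`. The run is deterministic
#' given `config@seed`.
#'
#' @param config a [SimulationConfig-class].
#' @return a [SimPullField-class] holding one [ImageStack-class] per channel
#'   and the per-molecule [GroundTruth-class].
#' @examples
#' cfg <- SimulationConfig(fieldWidthPx = 64, fieldHeightPx = 64,
#'                         nFrames = 12, surfaceDensity = 0.2, seed = 3)
#' fld <- simulateField(cfg)
#' fld
#' @export
simulateField <- function(config) {
    validObject(config)
    W <- config@fieldWidthPx; H <- config@fieldHeightPx
    T <- config@nFrames
    area <- fieldAreaUm2(config)
    totalDensity <- config@surfaceDensity +
        config@nChannels * config@nonspecificDensity +
        if (config@nChannels == 2L) config@partnerOnlyDensity else 0
    if (totalDensity * area > 0.5 * W * H)
        stop("expected molecule count exceeds half the field pixels: ",
             "unresolvable overlap regime")

    set.seed(config@seed)
    channels <- c("A", "B")[seq_len(config@nChannels)]
    mol <- list(); fluor <- list(); id <- 0L

    addMolecules <- function(n, channel, xy = NULL, nonspecific = FALSE,
                             coComplex = FALSE, ids = NULL) {
        if (n == 0L) return(invisible(NULL))
        chIdx <- match(channel, c("A", "B"))
        if (is.null(xy))
            xy <- cbind(stats::runif(n, 0.5, W + 0.5),
                        stats::runif(n, 0.5, H + 0.5))
        if (is.null(ids)) { ids <- id + seq_len(n); id <<- id + n }
        if (nonspecific) {
            copies <- rep(1L, n); flcop <- rep(1L, n)
        } else {
            p <- config@copyNumberDist[[chIdx]]
            copies <- sample.int(length(p), n, replace = TRUE, prob = p)
            flcop <- stats::rbinom(n, copies, config@maturationProb[chIdx])
        }
        mol[[length(mol) + 1L]] <<- data.frame(
            molecule = ids, channel = channel,
            x_px = xy[, 1], y_px = xy[, 2],
            copies = copies, fluorescent = flcop,
            is_nonspecific = nonspecific, is_co_complex = coComplex,
            stringsAsFactors = FALSE)
        tot <- sum(flcop)
        if (tot > 0L) {
            L <- drawEmissionLengths(tot, config@bleachProbPerFrame)
            fluor[[length(fluor) + 1L]] <<- data.frame(
                molecule = rep(ids, flcop), channel = channel,
                x_px = rep(xy[, 1], flcop), y_px = rep(xy[, 2], flcop),
                last_frame = L, stringsAsFactors = FALSE)
        }
        invisible(ids)
    }

    # specific complexes: always labeled in channel A
    nSpec <- stats::rpois(1L, config@surfaceDensity * area)
    xyA <- cbind(stats::runif(nSpec, 0.5, W + 0.5),
                 stats::runif(nSpec, 0.5, H + 0.5))
    if (nSpec > 0L) {
        isCo <- if (config@nChannels == 2L)
            stats::runif(nSpec) < config@coComplexFraction else rep(FALSE, nSpec)
        idsA <- id + seq_len(nSpec); id <- id + nSpec
        addMolecules(nSpec, "A", xy = xyA, coComplex = isCo, ids = idsA)
        if (any(isCo))
            addMolecules(sum(isCo), "B", xy = xyA[isCo, , drop = FALSE],
                         coComplex = TRUE, ids = idsA[isCo])
    }
    if (config@nChannels == 2L) {
        nBonly <- stats::rpois(1L, config@partnerOnlyDensity * area)
        addMolecules(nBonly, "B")
    }
    for (ch in channels) {
        nNs <- stats::rpois(1L, config@nonspecificDensity * area)
        addMolecules(nNs, ch, nonspecific = TRUE)
    }

    molecules <- if (length(mol)) do.call(rbind, mol) else
        data.frame(molecule = integer(), channel = character(),
                   x_px = numeric(), y_px = numeric(), copies = integer(),
                   fluorescent = integer(), is_nonspecific = logical(),
                   is_co_complex = logical(), stringsAsFactors = FALSE)
    fluorophores <- if (length(fluor)) do.call(rbind, fluor) else
        data.frame(molecule = integer(), channel = character(),
                   x_px = numeric(), y_px = numeric(),
                   last_frame = numeric(), stringsAsFactors = FALSE)

    stackList <- list()
    for (ch in channels) {
        fl <- fluorophores[fluorophores$channel == ch, , drop = FALSE]
        if (ch == "B" && nrow(fl)) {
            fl$x <- fl$x_px + config@channelOffsetPx[1]
            fl$y <- fl$y_px + config@channelOffsetPx[2]
        } else {
            fl$x <- fl$x_px; fl$y <- fl$y_px
        }
        signal <- array(0, dim = c(H, W, T))
        signal <- renderFluorophores(signal, fl, config)
        for (t in seq_len(T)) {
            lam <- signal[, , t] + config@backgroundLevel
            px <- stats::rpois(H * W, lam)
            if (config@readNoiseSd > 0)
                px <- px + stats::rnorm(H * W, 0, config@readNoiseSd)
            signal[, , t] <- pmax(px, 0)
        }
        stackList[[ch]] <- new("ImageStack", frames = signal, channel = ch,
                               pixelSizeNm = config@pixelSizeNm)
    }

    gtFluor <- fluorophores[, c("molecule", "channel", "last_frame")]
    gtFluor$bleach_frame <- gtFluor$last_frame + 1
    gtFluor$last_frame <- NULL
    gt <- new("GroundTruth", molecules = molecules, fluorophores = gtFluor)
    new("SimPullField", stacks = stackList, truth = gt, config = config)
}

#' Simulate an idealized photobleaching trace
#'
#' Generates the staircase intensity trajectory of a single immobilized
#' complex with `nFluorophores` active fluorophores: each emits
#' `unitIntensity` photons/frame for a geometric number of frames
#' (`bleachProbPerFrame`), so the trace descends in unit steps to zero.
#' Optional Gaussian noise can be added to produce step-fitting fixtures.
#' Draws come from the caller's RNG stream.
#'
#' @param nFluorophores number of active fluorophores (>= 0).
#' @param config a [SimulationConfig-class] supplying `nFrames`,
#'   `unitIntensity` and `bleachProbPerFrame`.
#' @param noiseSd additive Gaussian noise s.d. (photons); 0 for an ideal
#'   staircase.
#' @return an [IntensityTrace-class]; its `meta` records the true step
#'   frames (`meta$trueStepFrames`, last emitting frame of each fluorophore
#'   that bleaches within the movie) and `meta$nFluorophores`.
#' @examples
#' cfg <- SimulationConfig(nFrames = 200, bleachProbPerFrame = 0.02)
#' set.seed(1)
#' tr <- simulateTrace(2, cfg, noiseSd = 20)
#' @export
simulateTrace <- function(nFluorophores, config = SimulationConfig(),
                          noiseSd = 0) {
    stopifnot(nFluorophores >= 0)
    T <- config@nFrames
    L <- drawEmissionLengths(as.integer(nFluorophores),
                             config@bleachProbPerFrame)
    active <- if (length(L))
        vapply(seq_len(T), function(t) sum(L >= t), numeric(1)) else
        numeric(T)
    values <- active * config@unitIntensity
    if (noiseSd > 0) values <- values + stats::rnorm(T, 0, noiseSd)
    stepFrames <- sort(L[is.finite(L) & L < T])
    new("IntensityTrace", values = values, apertureRadiusPx = NA_real_,
        annulusPx = c(NA_real_, NA_real_), spot = list(),
        meta = list(trueStepFrames = stepFrames,
                    nFluorophores = as.integer(nFluorophores)))
}
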