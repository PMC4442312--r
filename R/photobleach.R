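#' Extract a background-corrected intensity trace for one spot
#'
#' Aperture photometry: for every frame, the trace value is the sum over a
#' circular aperture centered on the spot minus (aperture pixel count) times
#' the median of a surrounding background annulus. Background correction
#' uses only annulus pixels, so neighboring-spot bleed into the annulus is
#' suppressed by the median.
#'
#' @param stack an [ImageStack-class].
#' @param spot a one-row spot table (see [detectSpots()]) or any list with
#'   `x_px` and `y_px`.
#' @param apertureRadiusPx aperture radius in pixels (default 3).
#' @param annulusPx inner/outer background annulus radii (default `c(5, 7)`).
#' @return an [IntensityTrace-class] of length `nFrames`.
#' @examples
#' fld <- simulateField(SimulationConfig(fieldWidthPx = 48, fieldHeightPx = 48,
#'     nFrames = 60, surfaceDensity = 0.05, maturationProb = 1, seed = 5))
#' sp <- detectSpots(stacks(fld)$A)
#' if (nrow(sp)) tr <- extractTrace(stacks(fld)$A, sp[1, ])
#' @export
extractTrace <- function(stack, spot, apertureRadiusPx = 3,
                         annulusPx = c(5, 7)) {
    fr <- frames(stack)
    d <- dim(fr); H <- d[1]; W <- d[2]; T <- d[3]
    r0 <- round(spot$y_px); c0 <- round(spot$x_px)
    margin <- ceiling(annulusPx[2])
    if (r0 - margin < 1 || r0 + margin > H || c0 - margin < 1 ||
        c0 + margin > W)
        stop("spot too close to field border for aperture extraction")
    ap <- diskOffsets(apertureRadiusPx)
    an <- annulusOffsets(annulusPx[1], annulusPx[2])
    apLin <- (c0 + ap$dc - 1) * H + (r0 + ap$dr)
    anLin <- (c0 + an$dc - 1) * H + (r0 + an$dr)
    frameOff <- (seq_len(T) - 1) * H * W
    apMat <- matrix(fr[outer(apLin, frameOff, "+")], nrow = length(apLin))
    anMat <- matrix(fr[outer(anLin, frameOff, "+")], nrow = length(anLin))
    bgMed <- apply(anMat, 2, stats::median)
    values <- colSums(apMat) - length(apLin) * bgMed
    new("IntensityTrace", values = as.numeric(values),
        apertureRadiusPx = apertureRadiusPx, annulusPx = annulusPx,
        spot = as.list(spot), meta = list())
}

# residual sum of squares of segment y[i..j] around its mean, from prefix sums
segCost <- function(S, S2, i, j) {
    n <- j - i + 1
    s <- S[j + 1] - S[i]
    (S2[j + 1] - S2[i]) - s^2 / n
}

# best single split of segment [l, r]: returns c(gain, splitAfterFrame)
bestSplit <- function(S, S2, l, r) {
    if (r - l < 1L) return(c(0, NA))
    t <- l:(r - 1L)
    n1 <- t - l + 1; n2 <- r - t
    s1 <- S[t + 1] - S[l];     s2v <- S2[t + 1] - S2[l]
    sR <- S[r + 1] - S[t + 1]; s2R <- S2[r + 1] - S2[t + 1]
    cost <- (s2v - s1^2 / n1) + (s2R - sR^2 / n2)
    full <- segCost(S, S2, l, r)
    i <- which.min(cost)
    c(full - cost[i], t[i])
}

# coordinate-descent refinement: re-optimize each change point with the
# others held fixed, until no change point moves
refineCps <- function(S, S2, T, cps) {
    if (length(cps) < 1L) return(cps)
    repeat {
        moved <- FALSE
        for (i in seq_along(cps)) {
            lo <- if (i == 1L) 1L else cps[i - 1L] + 1L
            hi <- if (i == length(cps)) T else cps[i + 1L]
            cand <- bestSplit(S, S2, lo, hi)
            if (!is.na(cand[2]) && cand[2] != cps[i]) {
                cps[i] <- as.integer(cand[2]); moved <- TRUE
            }
        }
        if (!moved) break
    }
    cps
}

# plateau means and RSS for a set of change points (cp = last frame of plateau)
staircaseFit <- function(y, cps) {
    bounds <- c(0L, sort(cps), length(y))
    k <- length(bounds) - 1L
    levels <- numeric(k); rss <- 0
    for (i in seq_len(k)) {
        seg <- y[(bounds[i] + 1L):bounds[i + 1L]]
        levels[i] <- mean(seg)
        rss <- rss + sum((seg - levels[i])^2)
    }
    list(levels = levels, rss = rss, bounds = bounds)
}

#' Count photobleaching steps in an intensity trace
#'
#' Fits a piecewise-constant staircase by greedy binary segmentation:
#' change points are inserted one at a time at the split that most reduces
#' the residual sum of squares, and a new step is accepted only while the
#' Schwarz-type criterion `RSS + penalty * sigma^2 * k * log(T)` decreases
#' (`sigma` is a robust noise estimate from the trace's first differences,
#' `k` the step count, `T` the trace length). Steps smaller than
#' `minStepSize` and plateaus shorter than `minDwellFrames` are then pruned.
#' A fit is accepted only if all retained steps are downward and the final
#' plateau lies within 3 noise s.d. of zero (complete bleaching); otherwise
#' the trace is rejected with a reason (`no_full_bleach`, `too_many_steps`,
#' `upward_step`, `low_snr`). Valid traces never raise an error.
#'
#' @param trace an [IntensityTrace-class] or numeric vector.
#' @param maxSteps maximum number of steps fitted (default 5).
#' @param penalty dimensionless model-selection penalty weight (default 2,
#'   two parameters per change point).
#' @param minStepSize smallest believable step (photons); default
#'   `3 * sigma` (the conventional significance floor -- spurious-step
#'   control is the penalty's job, the floor only removes sub-noise steps).
#' @param minDwellFrames shortest believable plateau (frames, default 3).
#' @return a [StepFit-class].
#' @examples
#' y <- c(rep(200, 40), rep(100, 80), rep(0, 80))
#' countSteps(y)
#' @export
countSteps <- function(trace, maxSteps = 5L, penalty = 2,
                       minStepSize = NULL, minDwellFrames = 3L) {
    y <- if (is(trace, "IntensityTrace")) traceValues(trace) else
        as.numeric(trace)
    T <- length(y)
    if (T < 2L * minDwellFrames)
        stop("trace shorter than 2 * minDwellFrames")
    sigma <- robustNoiseSd(y)
    if (is.null(minStepSize)) minStepSize <- 3 * sigma
    S <- c(0, cumsum(y)); S2 <- c(0, cumsum(y^2))
    logT <- log(T)
    pen <- penalty * sigma^2 * logT

    cps <- integer(0)
    fit <- staircaseFit(y, cps)
    crit <- fit$rss
    tooMany <- FALSE
    repeat {
        bounds <- c(0L, cps, T)
        best <- c(0, NA)
        for (i in seq_len(length(bounds) - 1L)) {
            cand <- bestSplit(S, S2, bounds[i] + 1L, bounds[i + 1L])
            if (!is.na(cand[2]) && cand[1] > best[1]) best <- cand
        }
        if (is.na(best[2]) || best[1] <= 0) break
        newCrit <- (crit - pen * length(cps)) - best[1] +
            pen * (length(cps) + 1L)
        if (newCrit < crit - 1e-9 * max(1, abs(crit))) {
            if (length(cps) >= maxSteps) { tooMany <- TRUE; break }
            cps <- sort(c(cps, as.integer(best[2])))
            cps <- refineCps(S, S2, T, cps)
            crit <- staircaseFit(y, cps)$rss + pen * length(cps)
        } else break
    }

    # prune implausible steps: too small, or bounding a too-short plateau
    repeat {
        if (!length(cps)) break
        fit <- staircaseFit(y, cps)
        sizes <- diff(fit$levels)
        dwells <- diff(fit$bounds)
        shortPlateau <- which(dwells < minDwellFrames)
        bad <- abs(sizes) < minStepSize
        for (p in shortPlateau) {
            if (p > 1L) bad[p - 1L] <- TRUE
            if (p <= length(sizes)) bad[p] <- TRUE
        }
        if (!any(bad)) break
        drop <- which(bad)[which.min(abs(sizes)[bad])]
        cps <- refineCps(S, S2, T, cps[-drop])
    }

    fit <- staircaseFit(y, cps)
    sizes <- if (length(cps)) diff(fit$levels) else numeric(0)
    k <- length(cps)

    reason <- "none"; accepted <- TRUE
    if (k == 0L) {
        accepted <- FALSE; reason <- "no_full_bleach"
    } else if (tooMany) {
        accepted <- FALSE; reason <- "too_many_steps"
    } else if (any(sizes > 0)) {
        accepted <- FALSE; reason <- "upward_step"
    } else if (sigma > 0 && max(fit$levels) < 3 * sigma) {
        accepted <- FALSE; reason <- "low_snr"
    } else if (abs(fit$levels[k + 1L]) > 3 * sigma + 1e-6) {
        accepted <- FALSE; reason <- "no_full_bleach"
    }

    new("StepFit", nSteps = as.integer(k),
        stepFrames = as.integer(cps), stepSizes = as.numeric(sizes),
        plateaus = as.numeric(fit$levels), rss = fit$rss, noiseSd = sigma,
        accepted = accepted, reason = reason)
}

#' Exact minimum-RSS staircase segmentation (oracle)
#'
#' Dynamic-programming search over all change-point placements: for each
#' step count k = 0..`maxSteps` it returns the global minimum residual sum
#' of squares of a piecewise-constant fit with exactly k changes, identical
#' to brute-force enumeration of all change-point tuples. Quadratic in trace
#' length, intended for validating the greedy fitter on short traces.
#'
#' @param trace an [IntensityTrace-class] or numeric vector.
#' @param maxSteps largest step count searched (default 3).
#' @return list with `rss` (numeric, element k + 1 is the optimum with k
#'   steps) and `changePoints` (list of the optimal change-point sets, as
#'   last-frame-of-plateau indices).
#' @examples
#' y <- c(rep(100, 30), rep(0, 30)) + rnorm(60, 0, 5)
#' oracleStepFit(y, maxSteps = 2)$rss
#' @export
oracleStepFit <- function(trace, maxSteps = 3L) {
    y <- if (is(trace, "IntensityTrace")) traceValues(trace) else
        as.numeric(trace)
    T <- length(y)
    S <- c(0, cumsum(y)); S2 <- c(0, cumsum(y^2))
    cost1t <- function(t) {            # cost of y[1..t], vectorized over t
        (S2[t + 1] - S[t + 1]^2 / t)
    }
    K <- min(maxSteps, T - 1L)
    D <- matrix(Inf, nrow = K + 1L, ncol = T)
    B <- matrix(NA_integer_, nrow = K + 1L, ncol = T)
    D[1, ] <- cost1t(seq_len(T))
    if (K >= 1L) for (k in seq_len(K)) {
        for (t in (k + 1L):T) {
            s <- k:(t - 1L)
            n <- t - s
            sums <- S[t + 1] - S[s + 1]
            segc <- (S2[t + 1] - S2[s + 1]) - sums^2 / n
            tot <- D[k, s] + segc
            i <- which.min(tot)
            D[k + 1L, t] <- tot[i]
            B[k + 1L, t] <- s[i]
        }
    }
    cpsFor <- function(k) {
        cps <- integer(0); t <- T
        for (kk in seq_len(k)) {
            s <- B[k - kk + 2L, t]
            cps <- c(s, cps); t <- s
        }
        cps
    }
    list(rss = D[, T], changePoints = lapply(0:K, cpsFor))
}

#' Accumulate step fits into a population step distribution
#'
#' @param fits list of [StepFit-class] objects.
#' @return a [StepDistribution-class]: accepted traces histogrammed by step
#'   count, rejected traces tallied by reason. Accepted plus rejected always
#'   equals the number of input fits.
#' @examples
#' fits <- lapply(1:3, function(i)
#'     countSteps(c(rep(100, 50), rep(0, 50)) + rnorm(100, 0, 10)))
#' buildStepDistribution(fits)
#' @export
buildStepDistribution <- function(fits) {
    if (!length(fits)) stop("at least one step fit required")
    acc <- vapply(fits, isAccepted, logical(1))
    ns <- vapply(fits, nSteps, integer(1))
    reasons <- vapply(fits, function(f) f@reason, character(1))
    counts <- table(factor(ns[acc], levels = sort(unique(ns[acc]))))
    counts <- stats::setNames(as.integer(counts), names(counts))
    allReasons <- c("no_full_bleach", "too_many_steps", "upward_step",
                    "low_snr")
    rej <- vapply(allReasons, function(r) sum(!acc & reasons == r),
                  integer(1))
    new("StepDistribution", counts = counts, rejected = rej)
}
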