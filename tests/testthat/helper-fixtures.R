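# shared fixtures: small-geometry configs and hand-built stacks with known truth

# small field for fast unit tests
tinyConfig <- function(...) {
    args <- list(fieldWidthPx = 100L, fieldHeightPx = 100L, nFrames = 12L,
                 surfaceDensity = 0.2, maturationProb = 1,
                 nonspecificDensity = 0, bleachProbPerFrame = 0.001,
                 seed = 1L)
    args[names(list(...))] <- list(...)
    do.call(SimulationConfig, args)
}

# counting acquisition at full geometry: short movie, negligible bleaching
countingConfig <- function(...) {
    args <- list(nFrames = 12L, bleachProbPerFrame = 0.001,
                 maturationProb = 1, nonspecificDensity = 0, seed = 1L)
    args[names(list(...))] <- list(...)
    do.call(SimulationConfig, args)
}

# build an ImageStack from explicit fluorophore positions and lifetimes;
# deterministic signal, optional Poisson/read noise from the caller's RNG
buildStack <- function(x, y, lastFrame, config, noise = FALSE) {
    H <- config@fieldHeightPx; W <- config@fieldWidthPx
    T <- config@nFrames
    fl <- data.frame(x = x, y = y, last_frame = lastFrame)
    signal <- array(0, dim = c(H, W, T))
    signal <- SiMPullCount:::renderFluorophores(signal, fl, config)
    signal <- signal + config@backgroundLevel
    if (noise) {
        for (t in seq_len(T)) {
            px <- stats::rpois(H * W, signal[, , t])
            if (config@readNoiseSd > 0)
                px <- px + stats::rnorm(H * W, 0, config@readNoiseSd)
            signal[, , t] <- pmax(px, 0)
        }
    }
    new("ImageStack", frames = signal, channel = "A",
        pixelSizeNm = config@pixelSizeNm)
}

# greedy one-to-one matching of truth positions to detections within radius
matchToTruth <- function(xyTruth, spots, radius = 2) {
    nT <- nrow(xyTruth); nS <- nrow(spots)
    if (nT == 0L || nS == 0L)
        return(list(tp = 0L, recall = if (nT) 0 else NA_real_,
                    precision = if (nS) 0 else NA_real_))
    d2 <- outer(xyTruth[, 1], spots$x_px, "-")^2 +
          outer(xyTruth[, 2], spots$y_px, "-")^2
    cand <- which(d2 <= radius^2)
    ti <- (cand - 1L) %% nT + 1L
    si <- (cand - 1L) %/% nT + 1L
    o <- order(d2[cand])
    usedT <- logical(nT); usedS <- logical(nS); tp <- 0L
    for (k in o) {
        if (!usedT[ti[k]] && !usedS[si[k]]) {
            usedT[ti[k]] <- TRUE; usedS[si[k]] <- TRUE; tp <- tp + 1L
        }
    }
    list(tp = tp, recall = tp / nT, precision = tp / nS)
}

# positions >= minSep apart and >= border px from every edge (rejection sampling)
wellSeparatedPositions <- function(n, W, H, minSep = 5, border = 6) {
    xs <- numeric(0); ys <- numeric(0)
    while (length(xs) < n) {
        x <- stats::runif(1, border, W - border)
        y <- stats::runif(1, border, H - border)
        if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= minSep^2)) {
            xs <- c(xs, x); ys <- c(ys, y)
        }
    }
    cbind(x = xs, y = ys)
}

# exhaustive brute-force 2-change-point RSS minimum (independent of the
# package's DP/greedy code paths)
bruteForceTwoStepRss <- function(y, minSeg = 1L) {
    T <- length(y)
    S <- c(0, cumsum(y)); S2 <- c(0, cumsum(y^2))
    seg <- function(i, j) {
        n <- j - i + 1
        (S2[j + 1] - S2[i]) - (S[j + 1] - S[i])^2 / n
    }
    best <- Inf
    for (a in minSeg:(T - 2L * minSeg)) {
        left <- seg(1, a)
        b <- (a + minSeg):(T - minSeg)
        n2 <- b - a
        s2 <- S[b + 1] - S[a + 1]
        mid <- (S2[b + 1] - S2[a + 1]) - s2^2 / n2
        n3 <- T - b
        s3 <- S[T + 1] - S[b + 1]
        right <- (S2[T + 1] - S2[b + 1]) - s3^2 / n3
        best <- min(best, left + mid + right)
    }
    best
}

# sample an observed-step histogram from the visible-step model
sampleStepHistogram <- function(n, m, nTraces) {
    p <- visibleStepPmf(n, m)
    js <- sample(as.integer(names(p)), nTraces, replace = TRUE, prob = p)
    tab <- table(js)
    stats::setNames(as.numeric(tab), names(tab))
}
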