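test_that("aperture photometry is unbiased on background and steps with bleaching", {
    cfg <- tinyConfig(fieldWidthPx = 41L, fieldHeightPx = 41L, nFrames = 80L)
    spot <- data.frame(x_px = 21, y_px = 21)

    # background-only: trace mean indistinguishable from zero
    set.seed(51)
    bg <- buildStack(numeric(0), numeric(0), numeric(0), cfg, noise = TRUE)
    tr <- extractTrace(bg, spot)
    v <- traceValues(tr)
    expect_lt(abs(mean(v)), 3 * sd(v) / sqrt(length(v)))

    # noiseless monomer bleaching after frame 50
    stk <- buildStack(21, 21, 50, cfg, noise = FALSE)
    v <- traceValues(extractTrace(stk, spot))
    expect_equal(v[1:50], rep(cfg@unitIntensity, 50), tolerance = 0.02)
    expect_equal(v[51:80], rep(0, 30), tolerance = 1e-6)

    # matured dimer under shot noise: pre-bleach level = 2 x unit
    set.seed(52)
    stk2 <- buildStack(c(21, 21), c(21, 21), c(40, 60), cfg, noise = TRUE)
    v2 <- traceValues(extractTrace(stk2, spot))[1:40]
    sem <- sd(v2) / sqrt(40)
    expect_lt(abs(mean(v2) - 2 * cfg@unitIntensity), 3 * sem)

    # border spots cannot be extracted
    expect_error(extractTrace(stk, data.frame(x_px = 3, y_px = 21)),
                 "border")
})

test_that("step counting is exact on clean staircases and rejects pathologies", {
    y <- c(rep(200, 40), rep(100, 80), rep(0, 80))
    f <- countSteps(y)
    expect_true(isAccepted(f))
    expect_identical(nSteps(f), 2L)
    expect_identical(stepFrames(f), c(40L, 120L))
    expect_equal(stepSizes(f), c(-100, -100))
    expect_equal(f@plateaus, c(200, 100, 0))

    # constant trace: nothing bleaches
    fc <- countSteps(rep(100, 50))
    expect_false(isAccepted(fc))
    expect_identical(fc@reason, "no_full_bleach")

    # never reaches background
    fn <- countSteps(c(rep(200, 50), rep(100, 50)))
    expect_false(isAccepted(fn))
    expect_identical(fn@reason, "no_full_bleach")

    # an upward jump larger than the step floor (blinking-like) is rejected
    fu <- countSteps(c(rep(100, 40), rep(220, 40), rep(0, 40)))
    expect_false(isAccepted(fu))
    expect_identical(fu@reason, "upward_step")

    # more steps than the cap
    y8 <- rep(seq(800, 0, by = -100), each = 25)
    f8 <- countSteps(y8, maxSteps = 3)
    expect_false(isAccepted(f8))
    expect_identical(f8@reason, "too_many_steps")
})

test_that("noisy two-step staircases are recovered at SNR 5", {
    trueFrames <- c(40L, 120L)
    yBase <- c(rep(200, 40), rep(100, 80), rep(0, 80))
    set.seed(61)
    hits <- logical(500)
    for (i in 1:500) {
        f <- countSteps(yBase + rnorm(200, 0, 20))
        hits[i] <- isAccepted(f) && nSteps(f) == 2L &&
            all(abs(stepFrames(f) - trueFrames) <= 2)
    }
    expect_gte(mean(hits), 0.95)
})

test_that("the greedy fit attains the brute-force RSS optimum", {
    # independent oracle: exhaustive enumeration of all change-point pairs
    yBase <- c(rep(200, 40), rep(100, 80), rep(0, 80))
    set.seed(62)
    for (i in 1:25) {
        y <- yBase + rnorm(200, 0, 20)
        f <- countSteps(y)
        if (nSteps(f) != 2L) next
        brute <- bruteForceTwoStepRss(y)
        expect_lte(f@rss, brute * 1.01)
        # and the package's DP oracle agrees with plain enumeration
        expect_equal(oracleStepFit(y, 2)$rss[3], brute, tolerance = 1e-9)
    }
})

test_that("step distributions conserve traces and classify monomers", {
    fits <- list(countSteps(c(rep(100, 50), rep(0, 50))),
                 countSteps(rep(50, 40)),
                 countSteps(c(rep(200, 30), rep(100, 40), rep(0, 50))))
    d <- buildStepDistribution(fits)
    expect_identical(sum(stepCounts(d)) + sum(d@rejected), 3L)
    expect_identical(stepCounts(d), c("1" = 1L, "2" = 1L))

    # a monomer population at SNR 5 lands in the 1-step bin
    cfg <- SimulationConfig(nFrames = 400L, bleachProbPerFrame = 0.01)
    set.seed(63)
    fits <- lapply(1:200, function(i)
        countSteps(simulateTrace(1, cfg, noiseSd = 20)))
    d <- buildStepDistribution(fits)
    expect_identical(sum(stepCounts(d)) + sum(d@rejected), 200L)
    expect_gte(stepCounts(d)[["1"]] / sum(stepCounts(d)), 0.90)
})

test_that("traces shorter than two dwell windows are rejected up front", {
    expect_error(countSteps(c(1, 2, 3), minDwellFrames = 3), "shorter")
})
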