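spotTable <- function(x, y, field = 1, channel = "A") {
    n <- length(x)
    data.frame(field = rep_len(field, n), channel = rep_len(channel, n),
               x_px = x, y_px = y, intensity = rep_len(1, n),
               peak = rep_len(1, n), stringsAsFactors = FALSE)
}

test_that("channel registration shifts and round-trips exactly", {
    b <- spotTable(c(10, 20), c(5, 8), channel = "B")
    expect_identical(registerChannels(b, c(0, 0)), b)
    shifted <- registerChannels(b, c(1.5, -2))
    expect_equal(shifted$x_px, c(8.5, 18.5))
    expect_equal(shifted$y_px, c(7, 10))
    expect_equal(registerChannels(shifted, -c(1.5, -2)), b)
})

test_that("identical fields colocalize fully and empty channels give zero", {
    a <- spotTable(c(10, 30, 50), c(10, 30, 50))
    res <- colocalize(a, a)
    expect_equal(colocalizationPct(res), 100)
    expect_identical(perFieldStats(res)$matched, 3L)

    res0 <- colocalize(a, spotTable(numeric(0), numeric(0), channel = "B"))
    expect_equal(colocalizationPct(res0), 0)
    expect_gt(length(res0@flags), 0)
})

test_that("matching is one-to-one, closest-first, and label-symmetric", {
    # two A spots compete for one B spot: only one pair forms
    a <- spotTable(c(10, 11), c(10, 10))
    b <- spotTable(10.2, 10, channel = "B")
    res <- colocalize(a, b)
    expect_identical(perFieldStats(res)$matched, 1L)
    expect_identical(perFieldStats(res)$refChannel, "B")
    expect_equal(colocalizationPct(res), 100)   # denominator = lower density

    # swapping channels preserves the matched-pair count
    set.seed(81)
    a2 <- spotTable(runif(40, 1, 200), runif(40, 1, 200))
    b2 <- spotTable(runif(60, 1, 200), runif(60, 1, 200), channel = "B")
    m1 <- perFieldStats(colocalize(a2, b2))$matched
    m2 <- perFieldStats(colocalize(b2, a2))$matched
    expect_identical(m1, m2)
})

test_that("chance colocalization follows the Poisson overlap formula", {
    expect_equal(expectedChanceColocalization(0, 2), 0)
    expect_gt(expectedChanceColocalization(1e6, 2), 99.999)
    expect_equal(expectedChanceColocalization(0.004, 2),
                 100 * (1 - exp(-0.004 * pi * 4)), tolerance = 1e-12)

    # Monte-Carlo: independent Poisson fields at lambda_B = 0.004 /px^2
    set.seed(82)
    W <- 300
    ps <- vapply(1:30, function(i) {
        a <- spotTable(runif(45, 10, W - 10), runif(45, 10, W - 10))
        nB <- rpois(1, 0.004 * W^2)
        b <- spotTable(runif(nB, 1, W), runif(nB, 1, W), channel = "B")
        perFieldStats(colocalize(a, b, radiusPx = 2))$pct
    }, numeric(1))
    sem <- sd(ps) / sqrt(length(ps))
    expect_lt(abs(mean(ps) - expectedChanceColocalization(0.004, 2)), 3 * sem)
})

test_that("registration recovers colocalization lost to channel offset", {
    cfg <- tinyConfig(fieldWidthPx = 200L, fieldHeightPx = 200L,
                      surfaceDensity = 0.15, nChannels = 2L,
                      coComplexFraction = 0.6, channelOffsetPx = c(2, 3),
                      seed = 19)
    fld <- simulateField(cfg)
    spA <- detectSpots(stacks(fld)$A)
    spB <- detectSpots(stacks(fld)$B)
    before <- colocalizationPct(colocalize(spA, spB))
    after <- colocalizationPct(colocalize(spA,
        registerChannels(spB, cfg@channelOffsetPx)))
    expect_gt(after, before)
    expect_gt(after, 40)
})

test_that("condition comparison reports difference, ratio and z", {
    mk <- function(pcts) {
        pf <- data.frame(field = seq_along(pcts), nA = 50, nB = 100,
                         refChannel = "A", nRef = 50,
                         matched = as.integer(pcts / 2), pct = pcts)
        new("ColocalizationResult", perField = pf, radiusPx = 2,
            meanPct = mean(pcts), sdPct = sd(pcts),
            expectedChancePct = NA_real_, flags = character())
    }
    same <- compareConditions(mk(c(40, 42, 38)), mk(c(40, 42, 38)))
    expect_equal(same$difference, 0)
    expect_equal(same$ratio, 1)

    cmp <- compareConditions(mk(c(40, 42, 38, 41)), mk(c(20, 22, 18, 21)))
    expect_gt(cmp$z, 3)
    expect_equal(cmp$ratio, 40.25 / 20.25, tolerance = 1e-9)

    # single-field conditions carry no z-score
    one <- compareConditions(mk(40), mk(20))
    expect_true(is.na(one$z))
})
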