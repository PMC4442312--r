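test_that("an empty field is pure background noise with no molecules", {
    cfg <- tinyConfig(surfaceDensity = 0, nonspecificDensity = 0, seed = 3)
    fld <- simulateField(cfg)
    expect_identical(nrow(truth(fld)@molecules), 0L)
    fr <- frames(stacks(fld)$A)
    expect_true(all(fr >= 0))
    expect_equal(mean(fr), cfg@backgroundLevel, tolerance = 0.02)
    expect_identical(dim(fr), c(100L, 100L, 12L))
})

test_that("molecule count is Poisson with mean density x area", {
    # expected 100 molecules on a 225 um^2 field; Monte-Carlo over 200 seeds
    area <- 100 * 100 * 0.15^2
    cfg0 <- tinyConfig(surfaceDensity = 100 / area, nFrames = 2L)
    counts <- vapply(1:200, function(s) {
        cfg <- tinyConfig(surfaceDensity = 100 / area, nFrames = 2L, seed = s)
        nrow(truth(simulateField(cfg))@molecules)
    }, integer(1))
    sem <- sd(counts) / sqrt(length(counts))
    expect_lt(abs(mean(counts) - 100), 2 * sem + 1e-9)
    # Poisson: variance on the order of the mean
    expect_gt(var(counts), 60)
    expect_lt(var(counts), 150)
})

test_that("default geometry is one 5000 um^2 imaging area at 150 nm/px", {
    cfg <- SimulationConfig()
    expect_equal(cfg@pixelSizeNm, 150)
    expect_equal(fieldAreaUm2(cfg), 5000, tolerance = 0.005)
    # the 2-pixel colocalization criterion corresponds to ~300 nm
    expect_equal(2 * cfg@pixelSizeNm, 300)
})

test_that("the same seed reproduces stacks and ground truth bit-identically", {
    cfg <- tinyConfig(nChannels = 2L, coComplexFraction = 0.5, seed = 11)
    f1 <- simulateField(cfg)
    f2 <- simulateField(cfg)
    expect_identical(frames(stacks(f1)$A), frames(stacks(f2)$A))
    expect_identical(frames(stacks(f1)$B), frames(stacks(f2)$B))
    expect_identical(truth(f1)@molecules, truth(f2)@molecules)
    expect_identical(truth(f1)@fluorophores, truth(f2)@fluorophores)
})

test_that("shot noise is Poisson: pixel variance matches the mean", {
    cfg <- tinyConfig(surfaceDensity = 0, nonspecificDensity = 0,
                      readNoiseSd = 0, nFrames = 12L, seed = 8)
    fr <- frames(stacks(simulateField(cfg))$A)   # 1.2e5 background samples
    expect_equal(var(as.numeric(fr)) / mean(fr), 1, tolerance = 0.05)
})

test_that("an isolated monomer integrates to unitIntensity per frame", {
    cfg <- tinyConfig(fieldWidthPx = 41L, fieldHeightPx = 41L, nFrames = 50L)
    set.seed(21)
    stk <- buildStack(21, 21, Inf, cfg, noise = TRUE)
    fr <- frames(stk)
    ap <- SiMPullCount:::diskOffsets(5 * cfg@psfSigmaPx)
    perFrame <- vapply(seq_len(50), function(t) {
        f <- fr[, , t]
        sum(f[cbind(21 + ap$dr, 21 + ap$dc)]) - nrow(ap) * cfg@backgroundLevel
    }, numeric(1))
    sem <- sd(perFrame) / sqrt(length(perFrame))
    expect_lt(abs(mean(perFrame) - cfg@unitIntensity), 3 * sem)
})

test_that("overlap regime and bad geometry are rejected", {
    expect_error(simulateField(tinyConfig(surfaceDensity = 3000)),
                 "overlap")
    expect_error(SimulationConfig(fieldWidthPx = 0), "positive")
    expect_error(SimulationConfig(maturationProb = 1.2), "probabilit")
    expect_error(SimulationConfig(copyNumberDist = c(0.5, 0.2)), "summing")
})

test_that("simulated traces are staircases with geometric bleach times", {
    cfg <- SimulationConfig(nFrames = 300L, bleachProbPerFrame = 0.02,
                            unitIntensity = 100)
    tr0 <- simulateTrace(0, cfg)
    expect_true(all(traceValues(tr0) == 0))

    # noiseless trimer: exactly 3 downward unit steps
    set.seed(4)
    tr3 <- simulateTrace(3, cfg)
    v <- traceValues(tr3)
    drops <- which(diff(v) < 0)
    expect_identical(v[1], 300)
    expect_identical(sum(-diff(v)), 300)
    expect_true(all(-diff(v)[drops] %% 100 == 0))
    expect_equal(sort(unique(c(tr3@meta$trueStepFrames))),
                 sort(unique(drops)), ignore_attr = TRUE)

    # first-bleach frame of a 2-fluorophore system: min of two geometrics,
    # mean 1/(1 - 0.98^2) ~ 25.25
    set.seed(5)
    firsts <- vapply(1:10000, function(i) {
        tr <- simulateTrace(2, cfg)
        tr@meta$trueStepFrames[1]
    }, numeric(1))
    sem <- sd(firsts) / sqrt(length(firsts))
    expect_lt(abs(mean(firsts) - 1 / (1 - 0.98^2)), 3 * sem)
})

test_that("two-channel truth couples co-complexes at one surface position", {
    cfg <- tinyConfig(nChannels = 2L, coComplexFraction = 0.6,
                      surfaceDensity = 0.3, seed = 17)
    gt <- truth(simulateField(cfg))@molecules
    cc <- gt[gt$is_co_complex, ]
    expect_gt(nrow(cc), 0)
    for (id in unique(cc$molecule)) {
        e <- cc[cc$molecule == id, ]
        expect_setequal(e$channel, c("A", "B"))
        expect_equal(length(unique(e$x_px)), 1L)
    }
    expect_true(all(gt$fluorescent <= gt$copies))
})
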