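test_that("a single noiseless monomer is localized within half a pixel", {
    cfg <- tinyConfig(readNoiseSd = 0)
    stk <- buildStack(x = 40, y = 60, lastFrame = Inf, cfg, noise = FALSE)
    sp <- detectSpots(stk)
    expect_identical(nrow(sp), 1L)
    expect_lt(abs(sp$x_px - 40), 0.5)
    expect_lt(abs(sp$y_px - 60), 0.5)
    expect_gt(sp$intensity, 0)
})

test_that("pure-background fields produce at most one false spot at 5 sigma", {
    for (s in 1:3) {
        cfg <- countingConfig(surfaceDensity = 0, seed = 100 + s)
        sp <- detectSpots(stacks(simulateField(cfg))$A)
        expect_lte(nrow(sp), 1L)
    }
})

test_that("well-separated matured molecules are recovered with high fidelity", {
    cfg <- countingConfig()
    set.seed(31)
    xy <- wellSeparatedPositions(100, cfg@fieldWidthPx, cfg@fieldHeightPx)
    stk <- buildStack(xy[, 1], xy[, 2], rep(Inf, 100), cfg, noise = TRUE)
    sp <- detectSpots(stk)
    m <- matchToTruth(xy, sp)
    expect_gte(m$recall, 0.98)
    expect_gte(m$precision, 0.98)
})

test_that("detection is equivariant under integer translations", {
    cfg <- tinyConfig(fieldWidthPx = 120L, readNoiseSd = 0)
    x <- c(30, 55, 80); y <- c(25, 60, 40)
    sp0 <- detectSpots(buildStack(x, y, rep(Inf, 3), cfg, noise = FALSE))
    sp1 <- detectSpots(buildStack(x + 7, y - 5, rep(Inf, 3), cfg,
                                  noise = FALSE))
    o0 <- order(sp0$x_px); o1 <- order(sp1$x_px)
    expect_identical(nrow(sp0), 3L)
    expect_equal(sp1$x_px[o1], sp0$x_px[o0] + 7, tolerance = 1e-6)
    expect_equal(sp1$y_px[o1], sp0$y_px[o0] - 5, tolerance = 1e-6)
})

test_that("empty and degenerate stacks are rejected", {
    cfg <- tinyConfig()
    stk <- buildStack(50, 50, Inf, cfg)
    expect_error(detectSpots(stk, projectionFrames = 50), "fewer frames")
    sat <- new("ImageStack", frames = array(1000, dim = c(20, 20, 4)),
               channel = "A", pixelSizeNm = 150)
    expect_error(detectSpots(sat, projectionFrames = 4), "saturated")
})

test_that("field quantification gives the arithmetic mean and n-1 sd", {
    q1 <- FieldQuantification(c(5, 5, 5))
    expect_equal(fieldMean(q1), 5)
    expect_equal(fieldSD(q1), 0)
    q2 <- FieldQuantification(c(4, 6))
    expect_equal(fieldMean(q2), 5)
    expect_equal(fieldSD(q2), sqrt(2))
    expect_equal(nAreas(q2), 2L)

    # rescaling to the 5000 um^2 reference area
    tabs <- list(data.frame(field = 1, x_px = 1:10),
                 data.frame(field = 2, x_px = 1:14))
    q <- quantifyFields(tabs, fieldAreaUm2 = 2500)
    expect_equal(fieldCounts(q), c(20, 28))
})

test_that("replicate areas recover the configured surface density", {
    # expected 40 molecules per 2495 um^2 field -> ~80 per 5000 um^2
    area <- 333 * 333 * 0.15^2
    tabs <- lapply(1:20, function(i) {
        cfg <- countingConfig(fieldWidthPx = 333L, fieldHeightPx = 333L,
                              surfaceDensity = 40 / area, seed = 400 + i)
        detectSpots(stacks(simulateField(cfg))$A, field = i)
    })
    q <- quantifyFields(tabs, fieldAreaUm2 = area)
    sem <- fieldSD(q) / sqrt(nAreas(q))
    expect_lt(abs(fieldMean(q) - 40 * 5000 / area), 3 * sem)
})

test_that("specificity comparison flags enrichment over the control", {
    r <- compareToControl(FieldQuantification(c(95, 105)),
                          FieldQuantification(c(9, 11)))
    expect_equal(r$ratio, 10)
    expect_true(r$passesSpecificity)
    r2 <- compareToControl(FieldQuantification(c(10)),
                           FieldQuantification(c(10)))
    expect_equal(r2$ratio, 1)
    expect_false(r2$passesSpecificity)
    r3 <- compareToControl(FieldQuantification(c(10)),
                           FieldQuantification(c(0)))
    expect_true(r3$controlFloored)
    expect_true(is.finite(r3$ratio))
})

test_that("dilution normalization rescales counts multiplicatively", {
    q <- FieldQuantification(c(50, 60))
    n <- normalizeByDilution(q, 200)
    expect_equal(fieldCounts(n), c(10000, 12000))
    expect_equal(fieldSD(n), 200 * fieldSD(q))
    expect_equal(fieldCounts(normalizeByDilution(q, 1)), fieldCounts(q))
    expect_error(normalizeByDilution(q, 0), "> 0")
})

test_that("equal per-volume densities agree after dilution normalization", {
    # the same lysate diluted 200x vs 800x: 4x surface density ratio
    area <- 200 * 200 * 0.15^2
    quantAt <- function(density, seedBase) {
        tabs <- lapply(1:6, function(i) {
            cfg <- countingConfig(fieldWidthPx = 200L, fieldHeightPx = 200L,
                                  surfaceDensity = density, seed = seedBase + i)
            detectSpots(stacks(simulateField(cfg))$A, field = i)
        })
        quantifyFields(tabs, fieldAreaUm2 = area)
    }
    qWT <- normalizeByDilution(quantAt(0.16, 500), 200)
    qMut <- normalizeByDilution(quantAt(0.04, 520), 800)
    sem <- sqrt(fieldSD(qWT)^2 / 6 + fieldSD(qMut)^2 / 6)
    expect_lt(abs(fieldMean(qWT) - fieldMean(qMut)), 3 * sem)
})
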