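#' Register channel-B spots onto channel-A coordinates
#'
#' Subtracts the configured channel offset from channel-B positions; the
#' identity when the offset is zero. Applying the negated offset inverts the
#' registration.
#'
#' @param spots a spot table (see [detectSpots()]).
#' @param offsetPx length-2 numeric (x, y) offset to remove.
#' @return the spot table with shifted `x_px`, `y_px`.
#' @examples
#' sp <- data.frame(field = 1, channel = "B", x_px = 10, y_px = 20,
#'                  intensity = 1, peak = 1)
#' registerChannels(sp, c(1.5, -2))
#' @export
registerChannels <- function(spots, offsetPx) {
    stopifnot(length(offsetPx) == 2L, all(is.finite(offsetPx)))
    spots$x_px <- spots$x_px - offsetPx[1]
    spots$y_px <- spots$y_px - offsetPx[2]
    spots
}

# greedy one-to-one matching of candidate pairs within radius, closest first;
# ties at identical distance broken by spot index order
matchPairs <- function(xyA, xyB, radius) {
    nA <- nrow(xyA); nB <- nrow(xyB)
    if (nA == 0L || nB == 0L) return(0L)
    dx <- outer(xyA[, 1], xyB[, 1], "-")
    dy <- outer(xyA[, 2], xyB[, 2], "-")
    d2 <- dx * dx + dy * dy
    cand <- which(d2 <= radius^2)
    if (!length(cand)) return(0L)
    ai <- (cand - 1L) %% nA + 1L
    bi <- (cand - 1L) %/% nA + 1L
    o <- order(d2[cand], ai, bi)
    usedA <- logical(nA); usedB <- logical(nB); matched <- 0L
    for (k in o) {
        if (!usedA[ai[k]] && !usedB[bi[k]]) {
            usedA[ai[k]] <- TRUE; usedB[bi[k]] <- TRUE
            matched <- matched + 1L
        }
    }
    matched
}

#' Two-channel colocalization with the lower-density denominator
#'
#' Matches spots across channels one-to-one (candidate pairs within
#' `radiusPx` assigned greedily, closest first, each spot used once) and
#' reports, per field, the percentage of spots of the lower-density channel
#' that have a partner in the other channel -- the assay's convention, since
#' the two proteins are pulled down to different extents. Percentages are
#' aggregated across fields as mean and s.d. (n - 1). The default radius of
#' 2 pixels corresponds to a ~300 nm diffraction-limited spot at 150 nm/px.
#'
#' @param spotsA,spotsB spot tables (see [detectSpots()]); channel B should
#'   already be registered ([registerChannels()]).
#' @param radiusPx match radius in pixels (default 2).
#' @param fieldAreaPx2 optional field area in pixels^2; when given, the
#'   chance-colocalization expectation is computed from the denser channel's
#'   density via [expectedChanceColocalization()].
#' @return a [ColocalizationResult-class].
#' @examples
#' a <- data.frame(field = 1, channel = "A", x_px = c(10, 30),
#'                 y_px = c(10, 30), intensity = 1, peak = 1)
#' b <- data.frame(field = 1, channel = "B", x_px = c(10.5, 80),
#'                 y_px = c(9.8, 80), intensity = 1, peak = 1)
#' colocalize(a, b)
#' @export
colocalize <- function(spotsA, spotsB, radiusPx = 2, fieldAreaPx2 = NULL) {
    stopifnot(radiusPx > 0)
    fields <- sort(unique(c(spotsA$field, spotsB$field)))
    flags <- character(0)
    rows <- lapply(fields, function(f) {
        a <- spotsA[spotsA$field == f, , drop = FALSE]
        b <- spotsB[spotsB$field == f, , drop = FALSE]
        nA <- nrow(a); nB <- nrow(b)
        refChannel <- if (nA <= nB) "A" else "B"
        nRef <- min(nA, nB)
        matched <- matchPairs(cbind(a$x_px, a$y_px), cbind(b$x_px, b$y_px),
                              radiusPx)
        pct <- if (nRef == 0L) 0 else 100 * matched / nRef
        data.frame(field = f, nA = nA, nB = nB, refChannel = refChannel,
                   nRef = nRef, matched = matched, pct = pct,
                   stringsAsFactors = FALSE)
    })
    pf <- do.call(rbind, rows)
    if (is.null(pf)) pf <- data.frame(field = integer(), nA = integer(),
        nB = integer(), refChannel = character(), nRef = integer(),
        matched = integer(), pct = numeric(), stringsAsFactors = FALSE)
    if (any(pf$nRef == 0))
        flags <- c(flags, "channel with zero spots in >=1 field")
    chance <- NA_real_
    if (!is.null(fieldAreaPx2) && nrow(pf)) {
        denser <- mean(pmax(pf$nA, pf$nB)) / fieldAreaPx2
        chance <- expectedChanceColocalization(denser, radiusPx)
    }
    new("ColocalizationResult", perField = pf, radiusPx = radiusPx,
        meanPct = if (nrow(pf)) mean(pf$pct) else NA_real_,
        sdPct = if (nrow(pf) > 1L) stats::sd(pf$pct) else NA_real_,
        expectedChancePct = chance, flags = flags)
}

#' Chance colocalization of independent spot fields
#'
#' Under a spatial Poisson null, the probability that a reference spot has
#' at least one spot of the other (denser) channel within radius r is
#' `1 - exp(-lambda * pi * r^2)`; reported as a percentage.
#'
#' @param densityPerPx2 spots per pixel^2 of the denser channel.
#' @param radiusPx match radius in pixels.
#' @return chance colocalization percentage.
#' @examples
#' expectedChanceColocalization(0.004, 2)   # ~4.91
#' @export
expectedChanceColocalization <- function(densityPerPx2, radiusPx) {
    stopifnot(densityPerPx2 >= 0)
    100 * (1 - exp(-densityPerPx2 * pi * radiusPx^2))
}

#' Compare colocalization between two conditions
#'
#' The scaffold-loss readout: reports the difference and ratio of mean
#' colocalization percentages and a two-sample z-score computed from the
#' across-field standard deviations. With fewer than two fields in either
#' condition the s.d. is undefined and the z-score is omitted (NA).
#'
#' @param resultA,resultB [ColocalizationResult-class] objects (e.g. control
#'   and knock-down).
#' @return list with `difference` (A - B), `ratio` (A / B), `z`,
#'   `meanA`, `meanB`, `nFieldsA`, `nFieldsB`.
#' @examples
#' a <- new("ColocalizationResult", perField = data.frame(field = 1:3,
#'     nA = 10, nB = 20, refChannel = "A", nRef = 10, matched = c(4, 5, 4),
#'     pct = c(40, 50, 40)), radiusPx = 2, meanPct = 43.3, sdPct = 5.8,
#'     expectedChancePct = NA_real_, flags = character())
#' compareConditions(a, a)
#' @export
compareConditions <- function(resultA, resultB) {
    pa <- perFieldStats(resultA); pb <- perFieldStats(resultB)
    ma <- mean(pa$pct); mb <- mean(pb$pct)
    na <- nrow(pa); nb <- nrow(pb)
    z <- if (na >= 2L && nb >= 2L) {
        se <- sqrt(stats::var(pa$pct) / na + stats::var(pb$pct) / nb)
        if (se > 0) (ma - mb) / se else NA_real_
    } else NA_real_
    list(difference = ma - mb, ratio = ma / mb, z = z,
         meanA = ma, meanB = mb, nFieldsA = na, nFieldsB = nb)
}
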