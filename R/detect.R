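#' Detect diffraction-limited spots in an image stack
#'
#' Works on the average projection of the first `projectionFrames` frames
#' (detect before most fluorophores bleach). The background is estimated as
#' the median of the projection and its s.d. robustly as 1.4826 x MAD; local
#' maxima exceeding `background + thresholdFactor x s.d.` are kept, maxima
#' closer than `minSeparationPx` are merged to the brighter one, and each
#' retained maximum is refined to subpixel position by the intensity-weighted
#' centroid of its background-subtracted 5x5 neighborhood.
#'
#' @param stack an [ImageStack-class].
#' @param projectionFrames number of initial frames to average (default 10).
#' @param thresholdFactor detection threshold in multiples of the background
#'   s.d. (default 5).
#' @param minSeparationPx minimum separation between spots in pixels
#'   (default 3).
#' @param field integer field identifier recorded in the output.
#' @return a spot table: data.frame with columns `field`, `channel`, `x_px`,
#'   `y_px` (subpixel, x = column, y = row), `intensity` (background-
#'   subtracted integrated intensity over the 5x5 window) and `peak`
#'   (background-subtracted peak projection value).
#' @examples
#' fld <- simulateField(SimulationConfig(fieldWidthPx = 96, fieldHeightPx = 96,
#'     nFrames = 12, surfaceDensity = 0.1, maturationProb = 1, seed = 2))
#' spots <- detectSpots(stacks(fld)$A)
#' nrow(spots)
#' @export
detectSpots <- function(stack, projectionFrames = 10L, thresholdFactor = 5,
                        minSeparationPx = 3, field = 1L) {
    fr <- frames(stack)
    d <- dim(fr)
    if (d[3] < 1L || all(d[1:2] == 0)) stop("empty image stack")
    if (d[3] < projectionFrames)
        stop("stack has fewer frames than projectionFrames")
    proj <- rowMeans(fr[, , seq_len(projectionFrames), drop = FALSE], dims = 2)
    H <- d[1]; W <- d[2]
    bg <- stats::median(proj)
    bgsd <- stats::mad(proj)
    if (bgsd == 0) {
        if (stats::sd(proj) == 0 && proj[1] > 0 &&
            all(proj == max(proj)))
            stop("all frames saturated: detector overload")
        # noiseless synthetic input: fall back to a tiny positive scale
        bgsd <- max(stats::sd(proj) * 1e-6, .Machine$double.eps)
    }
    thr <- bg + thresholdFactor * bgsd

    # local maxima of the projection over the 8-neighborhood, including
    # border pixels (neighbors outside the field treated as -Inf)
    pad <- matrix(-Inf, H + 2L, W + 2L)
    pad[2:(H + 1L), 2:(W + 1L)] <- proj
    isMax <- proj > thr
    for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        nb <- pad[2:(H + 1L) + dr, 2:(W + 1L) + dc]
        isMax <- isMax & (proj >= nb)
    }
    idx <- which(isMax, arr.ind = TRUE)
    if (!nrow(idx)) {
        out <- emptySpotTable()
        return(out)
    }
    rows <- idx[, 1]; cols <- idx[, 2]
    vals <- proj[cbind(rows, cols)]

    # merge maxima closer than minSeparationPx to the brighter one
    o <- order(vals, decreasing = TRUE)
    rows <- rows[o]; cols <- cols[o]; vals <- vals[o]
    keep <- logical(length(rows))
    kr <- numeric(0); kc <- numeric(0)
    for (i in seq_along(rows)) {
        if (length(kr) == 0L ||
            all((kr - rows[i])^2 + (kc - cols[i])^2 >= minSeparationPx^2)) {
            keep[i] <- TRUE
            kr <- c(kr, rows[i]); kc <- c(kc, cols[i])
        }
    }
    rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]

    # subpixel refinement: intensity-weighted centroid of the 5x5 window
    # (clipped at the field border, where localization degrades gracefully)
    n <- length(rows)
    x <- numeric(n); y <- numeric(n); intens <- numeric(n)
    for (i in seq_len(n)) {
        rr <- max(1L, rows[i] - 2L):min(H, rows[i] + 2L)
        cc <- max(1L, cols[i] - 2L):min(W, cols[i] + 2L)
        w <- pmax(proj[rr, cc] - bg, 0)
        s <- sum(w)
        if (s <= 0) { x[i] <- cols[i]; y[i] <- rows[i]; intens[i] <- 0; next }
        y[i] <- sum(rowSums(w) * rr) / s
        x[i] <- sum(colSums(w) * cc) / s
        intens[i] <- s
    }
    data.frame(field = as.integer(field), channel = channelName(stack),
               x_px = x, y_px = y, intensity = intens, peak = vals - bg,
               stringsAsFactors = FALSE)
}

#' Quantify molecules per imaging area across replicate fields
#'
#' Counts spots per field and rescales each count to the reference imaging
#' area (5000 um^2 by default), so fields of any geometry are comparable.
#' The across-area mean and s.d. (n - 1 denominator) are available through
#' [fieldMean()] and [fieldSD()].
#'
#' @param spotTables a list of spot tables (one per field) as returned by
#'   [detectSpots()], or a single spot table whose `field` column defines
#'   the areas.
#' @param fieldAreaUm2 the true area of each simulated/imaged field in um^2.
#' @param referenceAreaUm2 the reporting area (default 5000 um^2).
#' @param channel channel label recorded in the result.
#' @return a [FieldQuantification-class].
#' @examples
#' FieldQuantification(c(4, 6))
#' @export
quantifyFields <- function(spotTables, fieldAreaUm2, referenceAreaUm2 = 5000,
                           channel = "A") {
    if (is.data.frame(spotTables))
        spotTables <- split(spotTables, spotTables$field)
    if (length(spotTables) < 1L) stop("at least one field required")
    counts <- vapply(spotTables, nrow, integer(1))
    counts <- counts * referenceAreaUm2 / fieldAreaUm2
    new("FieldQuantification", counts = as.numeric(counts),
        channel = channel, areaUm2 = referenceAreaUm2)
}

#' Construct a FieldQuantification from raw per-area counts
#'
#' @param counts numeric molecule counts per imaging area.
#' @param channel channel label.
#' @param areaUm2 imaging area the counts refer to.
#' @return a [FieldQuantification-class].
#' @export
FieldQuantification <- function(counts, channel = "A", areaUm2 = 5000) {
    new("FieldQuantification", counts = as.numeric(counts),
        channel = channel, areaUm2 = areaUm2)
}

#' Compare a pull-down quantification to its antibody control
#'
#' The specificity readout of the assay: the ratio of the sample's mean
#' molecules per area to the control's (e.g. an anti-HA mock pull-down).
#' A control mean below `epsilon` is floored at `epsilon` and flagged.
#'
#' @param sample,control [FieldQuantification-class] objects.
#' @param threshold minimum enrichment ratio to pass (default 5).
#' @param epsilon floor for the control mean (molecules per area).
#' @return list with `ratio`, `passesSpecificity`, `controlFloored`,
#'   `sampleMean`, `controlMean`, `threshold`.
#' @examples
#' compareToControl(FieldQuantification(c(95, 105)),
#'                  FieldQuantification(c(9, 11)))
#' @export
compareToControl <- function(sample, control, threshold = 5, epsilon = 0.5) {
    sm <- fieldMean(sample); cm <- fieldMean(control)
    floored <- cm < epsilon
    ratio <- sm / max(cm, epsilon)
    list(ratio = ratio, passesSpecificity = ratio >= threshold,
         controlFloored = floored, sampleMean = sm, controlMean = cm,
         threshold = threshold)
}

#' Rescale a quantification by its lysate dilution factor
#'
#' Lysates are diluted to reach a countable single-molecule surface density;
#' multiplying the per-area counts by the dilution factor puts differently
#' diluted conditions on a common per-volume scale (the s.d. scales
#' identically since it is computed from the scaled counts).
#'
#' @param quant a [FieldQuantification-class].
#' @param dilutionFactor fold dilution (> 0), e.g. 200.
#' @return a [FieldQuantification-class] with scaled counts.
#' @examples
#' normalizeByDilution(FieldQuantification(c(50)), 200)
#' @export
normalizeByDilution <- function(quant, dilutionFactor) {
    if (!is.numeric(dilutionFactor) || dilutionFactor <= 0)
        stop("dilutionFactor must be > 0")
    new("FieldQuantification", counts = fieldCounts(quant) * dilutionFactor,
        channel = channelName(quant), areaUm2 = quant@areaUm2)
}
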