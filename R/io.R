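# photon counts are stored as 16-bit TIFF with a fixed photons-per-unit
# scale, recorded here; raw counts in this assay stay far below the ceiling
.TIFF_SCALE <- 65535

#' Write an image stack as a multi-page TIFF
#'
#' Frames are written frame-major as 16-bit grayscale; photon counts are
#' divided by 65535 on write and multiplied back on read, so values
#' round-trip to within one part in 65535 of full scale.
#'
#' @param stack an [ImageStack-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeImageStack <- function(stack, path) {
    fr <- frames(stack)
    T <- dim(fr)[3]
    pages <- lapply(seq_len(T), function(t)
        pmin(fr[, , t] / .TIFF_SCALE, 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param channel channel label to record.
#' @param pixelSizeNm pixel size to record (nm/px).
#' @return an [ImageStack-class].
#' @export
readImageStack <- function(path, channel = "A", pixelSizeNm = 150) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
    fr <- array(0, dim = c(H, W, length(pages)))
    for (t in seq_along(pages)) fr[, , t] <- pages[[t]] * .TIFF_SCALE
    new("ImageStack", frames = fr, channel = channel,
        pixelSizeNm = pixelSizeNm)
}

#' Write or read a spot table as CSV
#'
#' Columns: `field`, `channel`, `x_px`, `y_px`, `intensity`, `peak`.
#'
#' @param spots a spot table (see [detectSpots()]).
#' @param path CSV file path.
#' @return `writeSpots` returns the path invisibly; `readSpots` the table.
#' @export
writeSpots <- function(spots, path) {
    utils::write.csv(spots, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSpots
#' @export
readSpots <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write ground truth to CSV (one row per molecule entry)
#'
#' The fluorophore-level bleach frames are folded in as a comma-separated
#' list per molecule/channel so the whole truth fits one flat table.
#'
#' @param gt a [GroundTruth-class].
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
writeGroundTruth <- function(gt, path) {
    m <- gt@molecules
    fl <- gt@fluorophores
    key <- paste(m$molecule, m$channel)
    bf <- split(fl$bleach_frame, paste(fl$molecule, fl$channel))
    m$bleach_frames <- vapply(key, function(k)
        paste(bf[[k]], collapse = ","), character(1), USE.NAMES = FALSE)
    utils::write.csv(m, path, row.names = FALSE)
    invisible(path)
}

# canonical YAML dump of a config for hashing and provenance
configToList <- function(config) {
    list(fieldWidthPx = config@fieldWidthPx,
         fieldHeightPx = config@fieldHeightPx,
         pixelSizeNm = config@pixelSizeNm, nFrames = config@nFrames,
         psfSigmaPx = config@psfSigmaPx,
         surfaceDensity = config@surfaceDensity,
         copyNumberDist = lapply(config@copyNumberDist, as.numeric),
         maturationProb = config@maturationProb,
         bleachProbPerFrame = config@bleachProbPerFrame,
         unitIntensity = config@unitIntensity,
         backgroundLevel = config@backgroundLevel,
         readNoiseSd = config@readNoiseSd,
         coComplexFraction = config@coComplexFraction,
         partnerOnlyDensity = config@partnerOnlyDensity,
         channelOffsetPx = config@channelOffsetPx,
         nonspecificDensity = config@nonspecificDensity,
         nChannels = config@nChannels, seed = config@seed)
}

#' Write a simulation configuration as YAML
#'
#' @param config a [SimulationConfig-class].
#' @param path YAML file path.
#' @return the path, invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
    yaml::write_yaml(configToList(config), path)
    invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file path.
#' @return a [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
    do.call(SimulationConfig, yaml::read_yaml(path))
}
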