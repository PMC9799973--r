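#' @include AllClasses.R synthetic.R segmentation.R straighten.R accumulation.R boundary.R
NULL

#' Pipeline run configuration
#'
#' All tunable parameters with their conventional defaults: 50 px band,
#' 3 px perpendicular line, 85% threshold, rolling period 3, 20%/60%
#' polar regions. Round-trips losslessly through JSON via
#' [writeRunConfig()] / [readRunConfig()].
#'
#' @param ... overrides for any default field.
#' @return a named list of parameters.
#' @export
runConfig <- function(...) {
  cfg <- list(
    blurSigma = 2,
    minArea = 500,
    backgroundMargin = 10,
    cortexMargin = 8,
    bandWidth = 50,
    lateralWidth = 3,
    thresholdFactor = 0.85,
    rollingPeriod = 3,
    basisDim = 20,
    initiationThreshold = 0.9,
    completionTol = 0.02,
    event = "anaphase",
    rngSeed = 1
  )
  utils::modifyList(cfg, list(...))
}

#' @rdname runConfig
#' @param config a configuration list from [runConfig()].
#' @param path file path for the JSON configuration.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- lapply(cfg, function(x) if (is.integer(x)) as.numeric(x) else x)
  utils::modifyList(runConfig(), cfg)
}

#' Simulate and write a synthetic embryo movie
#'
#' Renders all frames, writes them as a 16-bit multi-page TIFF, and writes
#' a JSON ground-truth sidecar holding every generator field, the anterior
#' pole, event times, a subsampled true contour, and the true accumulation
#' samples per frame.
#'
#' @param spec a [SyntheticEmbryoSpec-class].
#' @param truth an [AccumulationGroundTruth-class].
#' @param tiffPath output TIFF path.
#' @param sidecarPath output JSON path (default: TIFF path + ".json").
#' @param events named list of event times in seconds (frame clock).
#' @return invisibly, list(tiff, sidecar) of the written paths.
#' @export
simulateMovie <- function(spec, truth, tiffPath,
                          sidecarPath = paste0(tiffPath, ".json"),
                          events = list(NEBD = 0, anaphase = 0)) {
  frames <- lapply(seq_len(spec@nFrames), function(i)
    renderFrame(spec, truth, i))
  pages <- lapply(frames, function(f) pmin(intensity(f), 65535) / 65535)
  tiff::writeTIFF(pages, tiffPath, bits.per.sample = 16, compression = "none")

  sGrid <- seq(0, 1, length.out = 129L)[-129L]
  ctr <- trueContour(spec, 256L)
  sidecar <- list(
    imageShape = spec@imageShape, center = spec@center,
    semiAxes = spec@semiAxes, orientation = spec@orientation,
    anteriorEnd = spec@anteriorEnd, cortexWidth = spec@cortexWidth,
    backgroundLevel = spec@backgroundLevel,
    cytoplasmLevel = spec@cytoplasmLevel, noiseModel = spec@noiseModel,
    pixelSize = spec@pixelSize, frameInterval = spec@frameInterval,
    nFrames = spec@nFrames, rngSeed = spec@rngSeed,
    truth = list(baseline = truth@baseline,
                 anteriorGain = truth@anteriorGain,
                 depletionCenter = truth@depletionCenter,
                 depletionHalfWidth = truth@depletionHalfWidth,
                 depletionDepth = truth@depletionDepth,
                 edgeSteepness = truth@edgeSteepness,
                 temporalRamp = truth@temporalRamp),
    anteriorPole = as.numeric(anteriorPole(spec)),
    events = events,
    contour = list(s = arcFraction(ctr),
                   row = contourPoints(ctr)[, 1],
                   col = contourPoints(ctr)[, 2]),
    trueAccumulation = lapply(seq_len(spec@nFrames), function(i)
      trueProfile(truth, sGrid, i)),
    trueAccumulationS = sGrid)
  jsonlite::write_json(sidecar, sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(list(tiff = tiffPath, sidecar = sidecarPath))
}

#' Read a movie written by [simulateMovie()]
#'
#' @param tiffPath multi-page TIFF path.
#' @param sidecarPath JSON sidecar path.
#' @return list with \code{frames} (list of [ImageFrame-class], intensities
#'   restored to camera units) and \code{meta} (the parsed sidecar).
#' @export
readMovie <- function(tiffPath, sidecarPath = paste0(tiffPath, ".json")) {
  pages <- tiff::readTIFF(tiffPath, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  frames <- lapply(seq_along(pages), function(i)
    new("ImageFrame", intensity = pages[[i]] * 65535,
        pixelSize = meta$pixelSize,
        time = (i - 1) * meta$frameInterval, frameIndex = as.integer(i)))
  list(frames = frames, meta = meta)
}

#' Quantify cortical accumulation for one embryo
#'
#' Runs the full per-frame chain: segmentation, background and cytoplasm
#' estimation, sub-pixel contour extraction anchored at the anterior,
#' straightening into a 50 px band, the 3 px perpendicular maximum, and
#' cytoplasm normalization; then assembles the regional time series.
#'
#' @param frames list of [ImageFrame-class].
#' @param anteriorHint c(row, col) near the anterior pole.
#' @param config parameters from [runConfig()].
#' @return list with \code{timeSeries} ([EmbryoTimeSeries-class]),
#'   \code{profiles} (list of [AccumulationProfile-class]),
#'   \code{contours}, \code{background} and \code{cytoplasm} (per frame).
#' @export
quantifyEmbryo <- function(frames, anteriorHint, config = runConfig()) {
  profiles <- vector("list", length(frames))
  contours <- vector("list", length(frames))
  bg <- cyto <- numeric(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    mask <- segmentEmbryo(f, blurSigma = config$blurSigma,
                          minArea = config$minArea)
    bg[i] <- estimateBackground(f, mask, margin = config$backgroundMargin)
    cyto[i] <- estimateCytoplasm(f, mask, cortexMargin = config$cortexMargin)
    ctr <- anchorContour(extractContour(mask, pixelSize(f)), anteriorHint)
    band <- extractBand(f, ctr, bandWidth = config$bandWidth)
    raw <- maxDepthProfile(band, lateralWidth = config$lateralWidth)
    profiles[[i]] <- normalizeProfile(raw, bg[i], cyto[i],
                                      time = frameTime(f))
    contours[[i]] <- ctr
  }
  list(timeSeries = buildTimeSeries(profiles, contours,
                                    event = config$event),
       profiles = profiles, contours = contours,
       background = bg, cytoplasm = cyto)
}

#' Quantify a movie from disk and write CSV outputs
#'
#' Reads a TIFF + sidecar pair, quantifies it with the sidecar's anterior
#' pole as the hint, and writes two CSVs into \code{outDir}: a time series
#' (embryo_id, time_s, ant_mean, post_mean, ap_ratio, cortex_mean,
#' perimeter_norm) and a per-position profile table (embryo_id, time_s, s,
#' accumulation). Each CSV carries the producing parameter set as
#' \code{#}-prefixed header lines; reruns are byte-identical.
#'
#' @param tiffPath movie TIFF path.
#' @param outDir output directory (created if missing).
#' @param embryoId identifier written into the CSVs.
#' @param config parameters from [runConfig()].
#' @param sidecarPath JSON sidecar path.
#' @return invisibly, the [quantifyEmbryo()] result.
#' @export
quantifyMovie <- function(tiffPath, outDir, embryoId = "embryo1",
                          config = runConfig(),
                          sidecarPath = paste0(tiffPath, ".json")) {
  mov <- readMovie(tiffPath, sidecarPath)
  res <- quantifyEmbryo(mov$frames, anteriorHint = mov$meta$anteriorPole,
                        config = config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ts <- seriesData(res$timeSeries)
  tsOut <- data.frame(embryo_id = embryoId, time_s = ts$time,
                      ant_mean = ts$anteriorMean,
                      post_mean = ts$posteriorMean,
                      ap_ratio = ts$apRatio, cortex_mean = ts$cortexMean,
                      perimeter_norm = ts$perimeterNorm)
  writeMeasurementCsv(tsOut, file.path(outDir, "timeseries.csv"), config)
  prOut <- do.call(rbind, lapply(res$profiles, function(p)
    data.frame(embryo_id = embryoId, time_s = frameTime(p),
               s = arcFraction(p), accumulation = accumulation(p))))
  writeMeasurementCsv(prOut, file.path(outDir, "profiles.csv"), config)
  invisible(res)
}

#' Write a measurement CSV with a parameter header
#'
#' RFC-4180 CSV preceded by \code{#}-prefixed comment lines recording the
#' parameter set that produced the file.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param params named list of parameters to record.
#' @return invisibly, the path.
#' @export
writeMeasurementCsv <- function(df, path, params = list()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  flat <- unlist(params)
  writeLines(c(sprintf("# cortexQuant measurement"),
               sprintf("# %s=%s", names(flat), as.character(flat))),
             con)
  utils::write.table(df, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, qmethod = "double")
  invisible(path)
}
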