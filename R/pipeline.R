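# End-to-end microcalibration: sequential per-pixel application of the
# transfer and calibration models, biomass masking, image summaries, R2 and
# leave-one-out cross-validation.

#' Microcalibrate a hyperspectral cube
#'
#' Sequentially applies the transfer model (pixel spectrum -> bulk-domain
#' spectrum) and the calibration model (bulk-domain spectrum -> analyte
#' value) to every valid pixel, yielding a spatially resolved analyte map.
#' Deterministic at inference.
#'
#' @param cube a [HyperspectralCube-class].
#' @param transferModel trained transfer [TrainedModel-class].
#' @param calibrationModel trained calibration [TrainedModel-class].
#' @param zeroNegligible assign zero analyte to pixels whose raw signal is
#'   below `signalThreshold` (percent-of-biomass analytes are zero where
#'   there is no biomass; a regression output there is extrapolated noise).
#' @param signalThreshold signal cutoff in AU for the zero assignment.
#' @param signalWindow wavenumber window (cm^-1) of the signal metric.
#' @return object of class `"AnalyteMap"`: list with `values` (H x W,
#'   `NA` outside the mask), `mask`, `analyte`, `provenance`.
#' @export
microcalibrate <- function(cube, transferModel, calibrationModel,
                           zeroNegligible = TRUE, signalThreshold = 0.05,
                           signalWindow = c(1600, 1700)) {
  transferred <- applyTransfer(transferModel, cube)
  values <- predictValue(calibrationModel, transferred)
  if (isTRUE(zeroNegligible)) {
    # Pixels with negligible biomass carry no analyte: assign zero instead
    # of trusting a regression output extrapolated from noise.
    d <- dim(cube@data)
    M <- matrix(cube@data, d[1] * d[2], d[3])
    wn <- cube@grid@values
    win <- wn >= signalWindow[1] & wn <= signalWindow[2]
    signal <- apply(M[, win, drop = FALSE], 1, max)
    zero <- signal < signalThreshold & as.vector(cube@mask)
    values[matrix(zero, d[1], d[2])] <- 0
  }
  analyte <- if (!is.null(attr(calibrationModel, "analyte")))
    attr(calibrationModel, "analyte") else
      calibrationModel@provenance$analyte
  structure(list(values = values, mask = cube@mask,
                 analyte = if (is.null(analyte)) "analyte" else analyte,
                 provenance = list(
                   cube = cube@meta$sample_id,
                   transferHash = transferModel@provenance$dataHash,
                   calibrationHash = calibrationModel@provenance$dataHash)),
            class = "AnalyteMap")
}

#' @export
print.AnalyteMap <- function(x, ...) {
  cat(sprintf("AnalyteMap (%s): %d x %d, %d masked-in pixels\n", x$analyte,
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Mask out pixels with negligible biomass
#'
#' Restricts the map mask to pixels whose biomass signal (the QC signal
#' metric: maximum absorbance in the amide I window of the *raw* cube) is at
#' least `threshold`. Percent-of-biomass analytes are undefined where there
#' is no biomass, so such pixels are excluded from summaries.
#'
#' @param map an `"AnalyteMap"`.
#' @param cube the raw [HyperspectralCube-class] the map came from.
#' @param threshold signal threshold in AU (> 0); defaults to the QC signal
#'   threshold.
#' @param signalWindow wavenumber window of the signal metric.
#' @return the map with a restricted mask.
#' @export
maskNegligibleBiomass <- function(map, cube, threshold = 0.05,
                                  signalWindow = c(1600, 1700)) {
  if (threshold <= 0) stop("maskNegligibleBiomass: threshold must be > 0")
  d <- dim(cube@data)
  M <- matrix(cube@data, d[1] * d[2], d[3])
  sig <- .signalMetric(M, cube@grid@values, signalWindow)
  keep <- matrix(sig >= threshold, d[1], d[2])
  newMask <- map$mask & keep
  if (!any(newMask))
    warning("maskNegligibleBiomass: threshold removed every pixel")
  map$mask <- newMask
  map
}

#' Summarize an analyte map
#'
#' Arithmetic mean, population standard deviation and pixel count over the
#' masked-in pixels, plus an optional histogram. Pixels outside the mask
#' (empty pixels not covering the sample) are excluded.
#'
#' @param map an `"AnalyteMap"`.
#' @param bins number of histogram bins (0 disables the histogram).
#' @return list of class `"ImageSummary"`: `mean`, `sd`, `n`, and
#'   optionally `histogram` (list with `breaks`, `counts`).
#' @export
summarizeMap <- function(map, bins = 30) {
  v <- map$values[map$mask]
  v <- v[!is.na(v)]
  if (!length(v)) stop("summarizeMap: empty mask")
  out <- list(mean = mean(v),
              sd = sqrt(mean((v - mean(v))^2)),
              n = length(v))
  if (bins > 0) {
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    out$histogram <- list(breaks = h$breaks, counts = h$counts)
  }
  structure(out, class = "ImageSummary")
}

#' @export
print.ImageSummary <- function(x, ...) {
  cat(sprintf("ImageSummary: mean %.3f, sd %.3f, n %d\n", x$mean, x$sd,
              x$n))
  invisible(x)
}

#' Coefficient of determination against the identity line
#'
#' `R^2 = 1 - SS_res / SS_tot` with residuals of the predictions to the
#' reference values (identity-line convention) and total sum of squares
#' about the reference mean. The least-squares fit line of predictions on
#' references and its own squared correlation are also returned for
#' plotting and comparison.
#'
#' @param reference numeric reference values (variance > 0, length >= 3).
#' @param predictions numeric predictions, same length.
#' @return list with `r2`, `slope`, `intercept`, `r2Fit`.
#' @export
rSquared <- function(reference, predictions) {
  if (length(reference) < 3) stop("rSquared: need at least 3 pairs")
  if (length(reference) != length(predictions))
    stop("rSquared: length mismatch")
  ssTot <- sum((reference - mean(reference))^2)
  if (ssTot <= 0) stop("rSquared: reference variance is zero")
  ssRes <- sum((predictions - reference)^2)
  fit <- stats::lm.fit(cbind(1, reference), predictions)
  list(r2 = 1 - ssRes / ssTot,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       r2Fit = unname(stats::cor(reference, predictions)^2))
}

#' Leave-one-out cross-validation of the microcalibration pipeline
#'
#' For each held-out sample, a calibration model is trained on the remaining
#' samples' bulk spectra and reference values (the transfer model is trained
#' once on all homogenized data by default, or per fold in strict mode),
#' the held-out sample's homogenized cube is microcalibrated, and the
#' image-mean prediction is compared with the reference value; a pooled
#' `R^2` over all folds measures parameter recovery. The held-out sample's
#' bulk spectra, reference value and pixels never enter that fold's
#' calibration training (audited via sample ids).
#'
#' @param dataset a `"SyntheticDataset"` (or compatible list).
#' @param analyte analyte to evaluate (e.g. `"total_lipid"`).
#' @param transferModel a trained transfer model (required unless
#'   `strict = TRUE` with `transferArgs`).
#' @param calibSpec [networkSpec()] for the per-fold calibration models
#'   (default: small attention-augmented net on the dataset grid).
#' @param calibTrain [trainConfig()] for calibration training.
#' @param qc [qcConfig()] applied to each held-out cube before summarizing.
#' @param includeZeroFraction zero-pair fraction for calibration training.
#' @param calibAugment nuisance-augmented copies per calibration pair (see
#'   [buildCalibrationSet()]); augmentation keeps per-pixel predictions
#'   stable under the gain/baseline/noise residuals of transferred spectra.
#' @param seed integer seed.
#' @param strict retrain the transfer model inside every fold (slower;
#'   requires `transferArgs`, a list of arguments for
#'   [buildTransferPairs()] plus `spec` and `train` for the transfer net).
#' @param useIntact evaluate on the intact scenes instead of homogenized
#'   tiles (biomass-masked).
#' @return list of class `"EvaluationResult"`: per-sample data.frame
#'   (`sample_id`, `reference`, `imageMean`, `imageSd`, `n`), pooled `r2`,
#'   fit line, seeds and config echo.
#' @export
looCrossValidate <- function(dataset, analyte = "total_lipid",
                             transferModel = NULL, calibSpec = NULL,
                             calibTrain = NULL, qc = qcConfig(),
                             includeZeroFraction = 0.25, calibAugment = 5,
                             seed = 1, strict = FALSE, transferArgs = NULL,
                             useIntact = FALSE) {
  nS <- length(dataset$samples)
  if (nS < 4) stop("looCrossValidate: need at least 4 samples")
  grid <- dataset$grid
  K <- length(grid@values)
  if (is.null(calibSpec))
    calibSpec <- networkSpec(K, "calibration", channels = c(8, 8),
                             kernels = c(9, 7), attnHeads = 2, attnDim = 4,
                             hidden = 16)
  if (is.null(calibTrain))
    calibTrain <- trainConfig(lr = 2e-3, epochs = 120, batchSize = 8,
                              valFraction = 0, seed = childSeed(seed, "ct"))
  bulkAll <- .bulkTargets(dataset)
  rows <- list()
  failed <- character(0)
  for (i in seq_len(nS)) {
    held <- dataset$samples[[i]]
    trainIds <- vapply(dataset$samples[-i], `[[`, "", "id")
    stopifnot(!held$id %in% trainIds)  # audit: no leakage by id
    calSet <- buildCalibrationSet(
      bulkAll[-i], dataset$reference[dataset$reference$sample_id !=
                                       held$id, ],
      analyte, includeZeroFraction = includeZeroFraction,
      seed = childSeed(seed, "zero", i), nAugment = calibAugment)
    tm <- transferModel
    if (strict) {
      if (is.null(transferArgs))
        stop("looCrossValidate: strict mode needs transferArgs")
      foldData <- dataset
      foldData$samples <- dataset$samples[-i]
      pairs <- do.call(buildTransferPairs,
                       c(list(dataset = foldData), transferArgs$pairs,
                         list(seed = childSeed(seed, "tpairs", i))))
      tm <- trainModel(buildModel(transferArgs$spec,
                                  childSeed(seed, "tinit", i)),
                       pairs, transferArgs$train)
    }
    if (is.null(tm))
      stop("looCrossValidate: transferModel is required")
    cal <- trainModel(buildModel(calibSpec, childSeed(seed, "cinit", i)),
                      calSet, calibTrain)
    cal@provenance$analyte <- analyte
    res <- tryCatch({
      cube <- if (useIntact) held$intact$cube else held$homogenized
      cube <- qcFilter(cube, qc)$cube
      map <- microcalibrate(cube, tm, cal)
      sm <- summarizeMap(map, bins = 0)
      ref <- dataset$reference
      refv <- mean(ref$value[ref$sample_id == held$id &
                               ref$analyte == analyte])
      data.frame(sample_id = held$id, reference = refv,
                 imageMean = sm$mean, imageSd = sm$sd, n = sm$n)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, held$id)
      warning("fold ", held$id, " failed: ", conditionMessage(res))
    } else {
      rows[[length(rows) + 1]] <- res
    }
  }
  perSample <- do.call(rbind, rows)
  r2 <- rSquared(perSample$reference, perSample$imageMean)
  structure(list(perSample = perSample, r2 = r2$r2, fit = r2,
                 failedFolds = failed, analyte = analyte, seed = seed,
                 nFolds = nS, strict = strict, useIntact = useIntact),
            class = "EvaluationResult")
}

#' Evaluate a transfer model on held-out augmented pixels
#'
#' Measures how much closer the transfer model brings scatter-distorted
#' pixel spectra to the sample's bulk spectrum: for held-out QC-passing
#' pixels (disjoint from the training pixels when those are supplied via
#' `trainPairs`), each pixel is augmented once with simulated Mie
#' scattering, baseline and noise, and the spectral RMSE to the
#' replicate-averaged bulk spectrum is computed before and after applying
#' the transfer model.
#'
#' @param dataset a `"SyntheticDataset"`.
#' @param model trained transfer [TrainedModel-class].
#' @param config an [augmentationConfig()] for the held-out augmentation.
#' @param qc a [qcConfig()].
#' @param nPixelsPerSample held-out pixels per sample.
#' @param seed integer seed (distinct from the training-pair seed).
#' @param trainPairs optional `"TrainingSet"` whose pixels are excluded.
#' @return list with `medianRaw`, `medianTransferred`, `ratio`
#'   (`medianTransferred / medianRaw`), `n`, and per-pixel RMSE vectors.
#' @export
evaluateTransfer <- function(dataset, model, config = augmentationConfig(),
                             qc = qcConfig(), nPixelsPerSample = 8,
                             seed = 99, trainPairs = NULL) {
  grid <- dataset$grid
  targets <- .bulkTargets(dataset)
  rmseRaw <- numeric(0); rmseTr <- numeric(0)
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    flt <- qcFilter(s$homogenized, qc)
    d <- dim(flt$cube@data)
    M <- matrix(flt$cube@data, d[1] * d[2], d[3])
    validIdx <- which(as.vector(flt$cube@mask))
    if (!is.null(trainPairs))
      validIdx <- setdiff(validIdx,
                          trainPairs$pixel[trainPairs$sampleId == s$id])
    nPix <- min(nPixelsPerSample, length(validIdx))
    pick <- withSeed(childSeed(seed, "heldout", i), sample(validIdx, nPix))
    tgt <- absorbance(targets[[i]])
    for (p in pick) {
      aug <- augmentPixel(Spectrum(grid@values, M[p, ]), config,
                          seed = childSeed(seed, "haug", i, p))
      a <- absorbance(aug)
      tr <- .predictMatrix(model, matrix(a, 1))[1, ]
      rmseRaw <- c(rmseRaw, sqrt(mean((a - tgt)^2)))
      rmseTr <- c(rmseTr, sqrt(mean((tr - tgt)^2)))
    }
  }
  list(medianRaw = stats::median(rmseRaw),
       medianTransferred = stats::median(rmseTr),
       ratio = stats::median(rmseTr) / stats::median(rmseRaw),
       n = length(rmseRaw), rmseRaw = rmseRaw, rmseTransferred = rmseTr)
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf(
    "EvaluationResult (%s, %d folds%s): pooled R^2 = %.3f (fit R^2 = %.3f)\n",
    x$analyte, x$nFolds, if (x$useIntact) ", intact" else "",
    x$r2, x$fit$r2Fit))
  invisible(x)
}

#' Export pipeline outputs to a directory
#'
#' Writes, depending on the object: for an `"EvaluationResult"`, a summary
#' CSV (one row per sample), a reference-vs-prediction scatter PNG with
#' error bars and fit line, and a JSON run log; for an `"AnalyteMap"`, the
#' value matrix as CSV, a rendered PNG, and a histogram PNG. Re-exporting
#' identical inputs reproduces identical text outputs.
#'
#' @param x an `"EvaluationResult"` or `"AnalyteMap"`.
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of the files written, invisibly.
#' @export
exportOutputs <- function(x, outdir, prefix = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(x, "EvaluationResult")) {
    if (is.null(prefix)) prefix <- paste0("loo_", x$analyte)
    csv <- file.path(outdir, paste0(prefix, "_summary.csv"))
    utils::write.csv(x$perSample, csv, row.names = FALSE)
    png <- file.path(outdir, paste0(prefix, "_scatter.png"))
    grDevices::png(png, width = 720, height = 720)
    on.exit(grDevices::dev.off(), add = TRUE)
    with(x$perSample, {
      rng <- range(c(reference, imageMean - imageSd, imageMean + imageSd))
      plot(reference, imageMean, xlim = rng, ylim = rng,
           xlab = paste("reference", x$analyte),
           ylab = "image-mean prediction", pch = 19,
           main = sprintf("pooled R^2 = %.3f", x$r2))
      graphics::arrows(reference, imageMean - imageSd, reference,
                       imageMean + imageSd, angle = 90, code = 3,
                       length = 0.03)
      graphics::abline(0, 1, lty = 2, col = "grey40")
      graphics::abline(x$fit$intercept, x$fit$slope, col = "grey10")
    })
    log <- file.path(outdir, paste0(prefix, "_runlog.json"))
    jsonlite::write_json(list(analyte = x$analyte, r2 = x$r2,
                              fit = x$fit, nFolds = x$nFolds,
                              failedFolds = x$failedFolds, seed = x$seed),
                         log, auto_unbox = TRUE, digits = NA)
    files <- c(csv, png, log)
  } else if (inherits(x, "AnalyteMap")) {
    if (is.null(prefix)) prefix <- paste0("map_", x$analyte)
    csv <- file.path(outdir, paste0(prefix, ".csv"))
    v <- x$values
    v[!x$mask] <- NA
    utils::write.csv(v, csv, row.names = FALSE)
    png <- file.path(outdir, paste0(prefix, ".png"))
    grDevices::png(png, width = 640, height = 640)
    graphics::image(t(v[nrow(v):1, , drop = FALSE]), axes = FALSE,
                    main = x$analyte, useRaster = TRUE)
    grDevices::dev.off()
    hpng <- file.path(outdir, paste0(prefix, "_hist.png"))
    grDevices::png(hpng, width = 640, height = 480)
    graphics::hist(x$values[x$mask], breaks = 30,
                   xlab = x$analyte, main = "pixel distribution")
    grDevices::dev.off()
    files <- c(csv, png, hpng)
  } else stop("exportOutputs: unsupported object")
  invisible(files)
}
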