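# Physics-based augmentation of homogenized pixel spectra and the pixel
# exclusion (quality-control) rules used before transfer-model training.

#' Augmentation configuration
#'
#' Ranges for the simulated Mie-scattering draws (uniform within each
#' range) plus the polynomial-baseline and white-noise augmentation. The
#' radius and baseline-index ranges are the simulation ranges of the
#' scattering augmentation (r in 2-18 um, n0 in 1.2-1.65); aperture
#' half-angle, absorption weight, fill factor and the absorbance-to-n_i
#' scale are instrument/sample nuisances sampled within physically
#' reasonable bounds.
#'
#' @param radius sphere radius range, micrometres.
#' @param n0 constant real refractive-index range.
#' @param cAbs range of the absorption weight in `Q_ext^NA = c Q_abs +
#'   Q_sca^NA`.
#' @param thetaNA effective aperture half-angle range, radians.
#' @param kkScale range of the absorbance-to-`n_i` proportionality.
#' @param fillFactor sample/aperture cross-section ratio range.
#' @param baselineDegree maximum polynomial baseline degree.
#' @param baselineAmp maximum absolute baseline coefficient (AU).
#' @param noiseSd white-noise standard-deviation range (AU).
#' @param drawsPerPixel augmented draws per selected pixel.
#' @param forwardFraction fraction of draws that are the pure forward-model
#'   apparent absorbance (as intact pixels are), the rest being the clean
#'   spectrum plus the simulated scattering contribution.
#' @param scatterAmplitude severity range of the additive scattering
#'   contribution; the lower end of 0 means the training inputs span the
#'   whole severity continuum from undistorted (well-homogenized) pixels
#'   to fully distorted ones, so the trained model stays valid on clean
#'   homogenized pixels as well as on intact-sample pixels.
#' @return list of class `"AugmentationConfig"`.
#' @export
augmentationConfig <- function(radius = c(2, 18), n0 = c(1.2, 1.65),
                               cAbs = c(0.5, 1.5), thetaNA = c(0.05, 0.2),
                               kkScale = c(0.02, 0.1),
                               fillFactor = c(0.05, 0.25),
                               baselineDegree = 3, baselineAmp = 0.1,
                               noiseSd = c(0.001, 0.01), drawsPerPixel = 2,
                               forwardFraction = 0.5,
                               scatterAmplitude = c(0, 1)) {
  rng <- list(radius = radius, n0 = n0, cAbs = cAbs, thetaNA = thetaNA,
              kkScale = kkScale, fillFactor = fillFactor,
              noiseSd = noiseSd, scatterAmplitude = scatterAmplitude)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2 || r[1] > r[2])
      stop("augmentationConfig: invalid range for ", nm)
  }
  if (radius[1] <= 0 || thetaNA[1] < 0 || thetaNA[2] >= pi / 2 ||
      fillFactor[1] <= 0 || fillFactor[2] > 1 || cAbs[1] <= 0 ||
      scatterAmplitude[1] < 0)
    stop("augmentationConfig: ranges outside physical bounds")
  structure(c(rng, list(baselineDegree = baselineDegree,
                        baselineAmp = baselineAmp,
                        drawsPerPixel = drawsPerPixel,
                        forwardFraction = forwardFraction)),
            class = "AugmentationConfig")
}

#' Draw one distortion parameter set
#'
#' Independent uniform draws within the configured ranges; deterministic for
#' a fixed `(seed, drawIndex)`.
#'
#' @param config an [augmentationConfig()].
#' @param seed integer seed.
#' @param drawIndex index of the draw within the seed's stream.
#' @return list with `geometry` (a [MieGeometry-class]), `n0`, `kkScale`,
#'   `noiseSd`, `scatterAmplitude`, `baseline` coefficients and `forward`
#'   flag.
#' @export
sampleDistortion <- function(config, seed = 1, drawIndex = 1) {
  stopifnot(inherits(config, "AugmentationConfig"))
  withSeed(childSeed(seed, "distortion", drawIndex), {
    u <- function(r) stats::runif(1, r[1], r[2])
    list(
      geometry = MieGeometry(u(config$radius), thetaNA = u(config$thetaNA),
                             fillFactor = u(config$fillFactor),
                             cAbs = u(config$cAbs)),
      n0 = u(config$n0),
      kkScale = u(config$kkScale),
      noiseSd = u(config$noiseSd),
      scatterAmplitude = u(config$scatterAmplitude),
      baseline = stats::runif(config$baselineDegree + 1, -1, 1) *
        config$baselineAmp,
      forward = stats::runif(1) < config$forwardFraction)
  })
}

#' Augment one clean pixel spectrum
#'
#' Adds simulated Mie scattering (forward model of [distortSpectrum()] with
#' parameters drawn by [sampleDistortion()]), a random polynomial baseline
#' and Gaussian white noise. Depending on the draw, the output is either the
#' clean spectrum plus the simulated scattering contribution or the pure
#' forward-model apparent absorbance (emulating intact-sample pixels); with
#' `forwardFraction = 0`, zero amplitudes, `n0 = 1` and `kkScale = 0` the
#' augmentation is the identity. Deterministic per seed; the grid is never
#' resampled.
#'
#' @param clean a [Spectrum-class] (QC-passing homogenized pixel).
#' @param config an [augmentationConfig()].
#' @param seed integer seed.
#' @param drawIndex draw index (see [sampleDistortion()]).
#' @return a [Spectrum-class] on the same grid.
#' @export
augmentPixel <- function(clean, config, seed = 1, drawIndex = 1) {
  d <- sampleDistortion(config, seed, drawIndex)
  # measured pixel spectra carry noise and may dip slightly below zero;
  # the forward model needs a non-negative absorption spectrum for n_i
  cleanPos <- new("Spectrum", grid = clean@grid,
                  absorbance = pmax(absorbance(clean), 0),
                  meta = clean@meta)
  # Forward draws model a full biomass pixel: the non-particle fraction of
  # the pixel is absorbing matrix, not vacuum, so the chemical absorption
  # passes through alongside the Mie-scatter contribution.
  dist <- distortSpectrum(cleanPos, d$geometry, n0 = d$n0,
                          kkScale = d$kkScale,
                          matrixAbsorbance = if (d$forward)
                            absorbance(cleanPos) else NULL)
  base <- if (d$forward) absorbance(dist)
          else absorbance(clean) + d$scatterAmplitude * absorbance(dist)
  K <- length(base)
  tt <- seq(-1, 1, length.out = K)
  V <- t(vapply(0:config$baselineDegree, function(dd) tt^dd, numeric(K)))
  extra <- withSeed(childSeed(seed, "augnoise", drawIndex),
                    stats::rnorm(K, 0, d$noiseSd))
  out <- base + as.numeric(d$baseline %*% V) + extra
  new("Spectrum", grid = clean@grid, absorbance = out, meta = clean@meta)
}

#' Quality-control configuration
#'
#' Pixel exclusion rules for homogenized images: pixels with very poor
#' signal (default metric: maximum absorbance in the amide I window,
#' 1600-1700 cm^-1) and pixels deviating too much from the image mean
#' spectrum (default metric: 1 - Pearson correlation). The default
#' thresholds are this package's conservative choices, not values from any
#' reference instrument.
#'
#' @param signalWindow wavenumber window (cm^-1) of the signal metric.
#' @param signalMin minimum signal (AU).
#' @param deviationMax maximum `1 - r` against the image mean spectrum.
#' @return list of class `"QCConfig"`.
#' @export
qcConfig <- function(signalWindow = c(1600, 1700), signalMin = 0.05,
                     deviationMax = 0.2) {
  if (signalMin <= 0 || deviationMax <= 0)
    stop("qcConfig: thresholds must be positive")
  structure(list(signalWindow = signalWindow, signalMin = signalMin,
                 deviationMax = deviationMax), class = "QCConfig")
}

# Signal metric: max absorbance within the window, per pixel (rows of M).
.signalMetric <- function(M, wn, window) {
  cols <- which(wn >= window[1] & wn <= window[2])
  if (!length(cols)) stop("qc: signal window contains no grid points")
  apply(M[, cols, drop = FALSE], 1, max)
}

#' Pixel quality control of a hyperspectral cube
#'
#' Two-pass exclusion: first pixels below the signal threshold are removed,
#' then the image mean spectrum is recomputed over the survivors and pixels
#' whose deviation (1 - Pearson correlation to that mean) exceeds the
#' threshold are removed. QC only ever removes pixels (mask entries can flip
#' from valid to invalid, never the reverse).
#'
#' @param cube a [HyperspectralCube-class] with at least one valid pixel.
#' @param qc a [qcConfig()].
#' @return list with `cube` (mask updated) and `report` (counts per rule and
#'   the thresholds used).
#' @export
qcFilter <- function(cube, qc = qcConfig()) {
  mask <- cube@mask
  if (!any(mask)) stop("qcFilter: cube has no valid pixels")
  d <- dim(cube@data)
  M <- matrix(cube@data, d[1] * d[2], d[3])
  wn <- cube@grid@values
  valid <- as.vector(mask)
  sig <- .signalMetric(M, wn, qc$signalWindow)
  passSignal <- valid & sig >= qc$signalMin
  nSignalRemoved <- sum(valid & !passSignal)
  if (!any(passSignal))
    stop("qcFilter: all pixels removed by the signal rule")
  meanSpec <- colMeans(M[passSignal, , drop = FALSE])
  dev <- 1 - suppressWarnings(
    as.numeric(stats::cor(t(M), meanSpec)))
  dev[is.na(dev)] <- 1
  passDev <- passSignal & dev <= qc$deviationMax
  nDevRemoved <- sum(passSignal & !passDev)
  if (!any(passDev))
    stop("qcFilter: all pixels removed")
  newMask <- matrix(passDev, d[1], d[2])
  out <- cube
  out@mask <- newMask
  report <- list(nInput = sum(valid),
                 nSignalRemoved = nSignalRemoved,
                 nDeviationRemoved = nDevRemoved,
                 nRetained = sum(passDev),
                 thresholds = list(signalMin = qc$signalMin,
                                   deviationMax = qc$deviationMax,
                                   signalWindow = qc$signalWindow))
  list(cube = out, report = report)
}

#' Write a QC report as JSON
#'
#' @param report the `report` element returned by [qcFilter()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeQCReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Replicate-averaged bulk spectrum per sample, resampled to `grid`.
.bulkTargets <- function(dataset, averageReplicates = TRUE) {
  lapply(dataset$samples, function(s) {
    g <- dataset$grid
    mats <- vapply(s$bulk, function(b)
      absorbance(resampleToGrid(b, g)), numeric(length(g@values)))
    a <- if (averageReplicates) rowMeans(mats) else mats[, 1]
    Spectrum(g@values, a, sample_id = s$id, instrument = "macro")
  })
}

#' Build transfer-model training pairs
#'
#' QC-filters each sample's homogenized tile, samples pixels uniformly
#' without replacement, and augments each selected pixel
#' `config$drawsPerPixel` times; every augmented input targets the sample's
#' replicate-averaged bulk spectrum (resampled to the cube grid). A
#' configurable fraction of noise-only inputs paired with a zero target
#' teaches the transfer model the null mapping for empty pixels. Pairs are
#' shuffled deterministically.
#'
#' @param dataset a `"SyntheticDataset"` (or any list with the same shape).
#' @param config an [augmentationConfig()].
#' @param qc a [qcConfig()].
#' @param nPixelsPerSample pixels sampled per sample (all available, with a
#'   warning, if fewer pass QC).
#' @param seed integer seed.
#' @param includeZeroFraction fraction of additional zero pairs relative to
#'   the number of augmented pairs (default 0.1).
#' @param averageReplicates average technical bulk replicates before use as
#'   targets (default TRUE).
#' @param includeClean also pair every selected pixel's un-augmented
#'   measured spectrum with the bulk target (default TRUE). This is the
#'   core supervised pair of the homogenized-biomass bridge; the augmented
#'   draws extend it toward intact-like distortion severity.
#' @return object of class `"TrainingSet"`: list with matrices `x`
#'   (inputs) and `y` (targets), `grid`, `sampleId`, `pixel`,
#'   `task = "transfer"`.
#' @export
buildTransferPairs <- function(dataset, config = augmentationConfig(),
                               qc = qcConfig(), nPixelsPerSample = 16,
                               seed = 1, includeZeroFraction = 0.1,
                               averageReplicates = TRUE,
                               includeClean = TRUE) {
  grid <- dataset$grid
  K <- length(grid@values)
  targets <- .bulkTargets(dataset, averageReplicates)
  xs <- list(); ys <- list(); ids <- character(0); px <- integer(0)
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    flt <- qcFilter(s$homogenized, qc)
    d <- dim(flt$cube@data)
    M <- matrix(flt$cube@data, d[1] * d[2], d[3])
    validIdx <- which(as.vector(flt$cube@mask))
    nPix <- nPixelsPerSample
    if (length(validIdx) < nPix) {
      warning("buildTransferPairs: sample ", s$id, " has only ",
              length(validIdx), " QC-passing pixels (requested ", nPix, ")")
      nPix <- length(validIdx)
    }
    pick <- withSeed(childSeed(seed, "pick", i),
                     sample(validIdx, nPix))
    tgt <- absorbance(targets[[i]])
    for (p in seq_along(pick)) {
      clean <- Spectrum(grid@values, M[pick[p], ])
      if (includeClean) {
        xs[[length(xs) + 1]] <- absorbance(clean)
        ys[[length(ys) + 1]] <- tgt
        ids <- c(ids, s$id)
        px <- c(px, pick[p])
      }
      for (dr in seq_len(config$drawsPerPixel)) {
        aug <- augmentPixel(clean, config,
                            seed = childSeed(seed, "aug", i, pick[p]),
                            drawIndex = dr)
        xs[[length(xs) + 1]] <- absorbance(aug)
        ys[[length(ys) + 1]] <- tgt
        ids <- c(ids, s$id)
        px <- c(px, pick[p])
      }
    }
  }
  nReg <- length(xs)
  nZero <- round(includeZeroFraction * nReg)
  if (nZero > 0) {
    zero <- Spectrum(grid@values, numeric(K))
    for (z in seq_len(nZero)) {
      zin <- applyInstrument(zero, "micro",
                             seed = childSeed(seed, "zerox", z))
      xs[[length(xs) + 1]] <- absorbance(zin)
      ys[[length(ys) + 1]] <- numeric(K)
      ids <- c(ids, "ZERO")
      px <- c(px, 0L)
    }
  }
  X <- do.call(rbind, xs)
  Y <- do.call(rbind, ys)
  ord <- withSeed(childSeed(seed, "shuffle"), sample(nrow(X)))
  structure(list(x = X[ord, , drop = FALSE], y = Y[ord, , drop = FALSE],
                 grid = grid, sampleId = ids[ord], pixel = px[ord],
                 task = "transfer"),
            class = "TrainingSet")
}

#' Build a calibration training set
#'
#' Pairs each sample's (replicate-averaged) bulk spectrum with its reference
#' value for one analyte. A configured fraction of near-zero-signal spectra
#' (instrument noise on a zero spectrum) with target 0 teaches the model to
#' assign zero to pixels lacking biological material.
#'
#' @param bulkSpectra list of bulk [Spectrum-class] objects with
#'   `sample_id` (and optionally `replicate`) metadata, all on one grid.
#' @param references reference data.frame (see [readReferenceTable()]).
#' @param analyte analyte name to calibrate (e.g. `"total_lipid"`).
#' @param includeZeroFraction added zero pairs as a fraction of the sample
#'   count (default 0).
#' @param seed integer seed for the zero-pair noise.
#' @param averageReplicates average replicate spectra per sample.
#' @param nAugment nuisance-augmented copies added per pair (default 0).
#'   Each copy is `gain * x + polynomial baseline + white noise` with the
#'   same analyte value: a multiplicative gain (optical pathlength) change,
#'   a smooth baseline and noise all leave the composition unchanged, so
#'   these copies teach the calibration model invariance to exactly the
#'   nuisance modes that transferred pixel spectra still carry.
#' @param gainSd standard deviation of the log gain for augmented copies.
#' @param baselineAmp maximum absolute baseline coefficient (AU).
#' @param baselineDegree polynomial baseline degree.
#' @param noiseSd white-noise standard deviation (AU).
#' @return `"TrainingSet"` with matrix `x`, numeric `y`,
#'   `task = "calibration"`.
#' @export
buildCalibrationSet <- function(bulkSpectra, references, analyte,
                                includeZeroFraction = 0, seed = 1,
                                averageReplicates = TRUE, nAugment = 0,
                                gainSd = 0.1, baselineAmp = 0.1,
                                baselineDegree = 3, noiseSd = 0.005) {
  references <- validateReferenceTable(references)
  ids <- vapply(bulkSpectra, function(s)
    as.character(s@meta$sample_id), "")
  grid <- bulkSpectra[[1]]@grid
  uids <- unique(ids)
  xs <- list(); ys <- numeric(0); outIds <- character(0)
  for (u in uids) {
    rows <- which(ids == u)
    a <- vapply(bulkSpectra[rows], absorbance,
                numeric(length(grid@values)))
    xvec <- if (averageReplicates) rowMeans(a) else a[, 1]
    ref <- references[references$sample_id == u &
                        references$analyte == analyte, ]
    if (nrow(ref) == 0)
      stop("buildCalibrationSet: no ", analyte, " reference for sample ", u)
    xs[[length(xs) + 1]] <- xvec
    ys <- c(ys, mean(ref$value))
    outIds <- c(outIds, u)
  }
  nZero <- round(includeZeroFraction * length(uids))
  if (nZero > 0) {
    zero <- Spectrum(grid@values, numeric(length(grid@values)))
    for (z in seq_len(nZero)) {
      zin <- applyInstrument(zero, "macro",
                             seed = childSeed(seed, "zerocal", z))
      xs[[length(xs) + 1]] <- absorbance(zin)
      ys <- c(ys, 0)
      outIds <- c(outIds, "ZERO")
    }
  }
  if (nAugment > 0) {
    K <- length(grid@values)
    tt <- seq(-1, 1, length.out = K)
    V <- t(vapply(0:baselineDegree, function(dd) tt^dd, numeric(K)))
    nBase <- length(xs)
    for (j in seq_len(nBase)) {
      for (a in seq_len(nAugment)) {
        pert <- withSeed(childSeed(seed, "calaug", j, a), {
          gain <- exp(stats::rnorm(1, 0, gainSd))
          coef <- stats::runif(baselineDegree + 1, -1, 1) * baselineAmp
          noise <- stats::rnorm(K, 0, noiseSd)
          gain * xs[[j]] + as.numeric(coef %*% V) + noise
        })
        xs[[length(xs) + 1]] <- pert
        ys <- c(ys, ys[j])
        outIds <- c(outIds, outIds[j])
      }
    }
  }
  structure(list(x = do.call(rbind, xs), y = ys, grid = grid,
                 sampleId = outIds, analyte = analyte,
                 task = "calibration"),
            class = "TrainingSet")
}

#' @export
print.TrainingSet <- function(x, ...) {
  cat(sprintf("TrainingSet (%s): %d pairs, input length %d%s\n", x$task,
              nrow(x$x), ncol(x$x),
              if (x$task == "calibration")
                paste0(", analyte ", x$analyte) else ""))
  invisible(x)
}
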