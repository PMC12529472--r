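# Public model API: attention-augmented 1-D convolutional networks for the
# transfer task (pixel spectrum -> bulk-domain spectrum) and the calibration
# task (bulk-domain spectrum -> analyte value), trained with RMSProp on the
# mean-squared error.

#' Network architecture specification
#'
#' Convolution blocks (same-padded 1-D convolutions + ReLU) over the
#' wavenumber axis whose features are, after block `attnAfter`, concatenated
#' with multi-head self-attention features computed over the wavenumber
#' positions. The transfer head is a 1x1 convolution over the concatenated
#' features plus a skip channel carrying the standardized input, giving an
#' output on the same grid as the input; the calibration head mean-pools
#' over positions and applies a small dense network to a scalar (or short
#' vector) output.
#'
#' @param inputLength grid length K the model operates on.
#' @param task `"transfer"` or `"calibration"`.
#' @param channels conv channels per block.
#' @param kernels odd kernel widths per block.
#' @param attnHeads number of self-attention heads (0 disables attention).
#' @param attnDim per-head query/key/value dimension.
#' @param attnAfter index of the conv block after which attention features
#'   are concatenated (default: last block).
#' @param hidden dense hidden width of the calibration head.
#' @param nOut number of outputs of the calibration head (1 for
#'   single-target models, the default; multitarget behind this knob).
#' @return list of class `"NetworkSpec"`.
#' @export
networkSpec <- function(inputLength, task = c("transfer", "calibration"),
                        channels = c(8, 16, 16), kernels = c(9, 7, 5),
                        attnHeads = 2, attnDim = 8, attnAfter = NULL,
                        hidden = 32, nOut = 1) {
  task <- match.arg(task)
  if (length(channels) != length(kernels))
    stop("networkSpec: channels and kernels must have equal length")
  if (any(kernels %% 2 != 1)) stop("networkSpec: kernels must be odd")
  if (any(c(channels, kernels, inputLength, hidden, nOut) <= 0))
    stop("networkSpec: all sizes must be positive")
  if (is.null(attnAfter)) attnAfter <- length(channels)
  structure(list(inputLength = as.integer(inputLength), task = task,
                 channels = as.integer(channels),
                 kernels = as.integer(kernels),
                 attnHeads = as.integer(attnHeads),
                 attnDim = as.integer(attnDim),
                 attnAfter = as.integer(attnAfter),
                 hidden = as.integer(hidden), nOut = as.integer(nOut)),
            class = "NetworkSpec")
}

#' Build an untrained model
#'
#' Parameters are initialized deterministically from the seed (He/Glorot
#' scaling); normalization statistics are fitted later by [trainModel()].
#'
#' @param spec a [networkSpec()].
#' @param seed integer seed.
#' @return a [TrainedModel-class] (untrained).
#' @export
buildModel <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "NetworkSpec"))
  params <- .nnInit(spec, seed)
  new("TrainedModel", spec = unclass(spec), params = params,
      norm = list(), log = list(trained = FALSE),
      provenance = list(initSeed = seed))
}

#' Count model parameters
#'
#' @param model a [TrainedModel-class].
#' @return integer number of scalar parameters.
#' @export
nParameters <- function(model) {
  sum(vapply(model@params, length, integer(1)))
}

#' Training configuration
#'
#' RMSProp minimizing the mean-squared error, with a held-out validation
#' split and early stopping (epoch budgets for this method are not fixed a
#' priori, so the best-validation parameters are kept).
#'
#' @param lr learning rate.
#' @param decay RMSProp moving-average decay.
#' @param batchSize minibatch size.
#' @param epochs maximum epochs (>= 0; 0 leaves parameters unchanged).
#' @param valFraction held-out validation fraction (0 disables).
#' @param patience early-stopping patience in epochs.
#' @param seed integer seed controlling the split and batch order.
#' @return list of class `"TrainConfig"`.
#' @export
trainConfig <- function(lr = 1e-3, decay = 0.9, batchSize = 32,
                        epochs = 200, valFraction = 0.15, patience = 40,
                        seed = 1) {
  if (lr <= 0) stop("trainConfig: lr must be positive")
  if (epochs < 0) stop("trainConfig: epochs must be >= 0")
  structure(list(lr = lr, decay = decay, batchSize = batchSize,
                 epochs = epochs, valFraction = valFraction,
                 patience = patience, seed = seed), class = "TrainConfig")
}

# Cheap deterministic fingerprint of the training data for provenance.
.dataHash <- function(x, y) {
  s <- c(dim(x), sum(x), sum(x^2), length(y), sum(y), sum(y^2))
  paste(formatC(s, digits = 12, format = "g"), collapse = "/")
}

.normalizeX <- function(x, norm) {
  sweep(sweep(x, 2, norm$xMean), 2, norm$xSd, "/")
}

#' Train a model on a training set
#'
#' Fits per-wavenumber input standardization and target scaling (min-max
#' for spectrum targets, z-scaling for analyte targets) on the training
#' split only, then minimizes the mean-squared error with RMSProp.
#' Deterministic for fixed `(model, pairs, config)`.
#'
#' @param model a [TrainedModel-class] from [buildModel()].
#' @param pairs a `"TrainingSet"` from [buildTransferPairs()] or
#'   [buildCalibrationSet()] (or a list with `x`, `y`, `grid`, `task`).
#' @param config a [trainConfig()].
#' @return the trained [TrainedModel-class] (training log in `@log`).
#' @export
trainModel <- function(model, pairs, config = trainConfig()) {
  spec <- model@spec
  if (pairs$task != spec$task)
    stop("trainModel: training-set task (", pairs$task,
         ") does not match model task (", spec$task, ")")
  x <- pairs$x
  y <- if (spec$task == "transfer") pairs$y else
    matrix(pairs$y, ncol = spec$nOut)
  if (nrow(x) < 8) stop("trainModel: need at least 8 pairs")
  if (ncol(x) != spec$inputLength)
    stop("trainModel: input length ", ncol(x),
         " does not match model grid length ", spec$inputLength)
  n <- nrow(x)
  idx <- withSeed(childSeed(config$seed, "valsplit"), sample(n))
  nVal <- floor(config$valFraction * n)
  valIdx <- if (nVal >= 1) idx[seq_len(nVal)] else integer(0)
  trIdx <- setdiff(idx, valIdx)
  # normalization fitted on the training split only, then frozen
  xMean <- colMeans(x[trIdx, , drop = FALSE])
  xSd <- pmax(apply(x[trIdx, , drop = FALSE], 2, stats::sd), 1e-8)
  norm <- list(xMean = xMean, xSd = xSd,
               wavenumbers = pairs$grid@values)
  if (spec$task == "transfer") {
    yMin <- min(y[trIdx, ]); yMax <- max(y[trIdx, ])
    norm$yMin <- yMin
    norm$yScale <- max(yMax - yMin, 1e-8)
    yN <- (y - yMin) / norm$yScale
  } else {
    norm$yMean <- colMeans(y[trIdx, , drop = FALSE])
    norm$ySd <- pmax(apply(y[trIdx, , drop = FALSE], 2, stats::sd), 1e-8)
    yN <- sweep(sweep(y, 2, norm$yMean), 2, norm$ySd, "/")
  }
  xN <- .normalizeX(x, norm)
  params <- model@params
  state <- list()
  mseOf <- function(ids, ps) {
    p <- .nnForward(xN[ids, , drop = FALSE], ps, spec)$pred
    mean((p - yN[ids, , drop = FALSE])^2)
  }
  best <- params
  bestVal <- if (length(valIdx)) mseOf(valIdx, params) else Inf
  initialTrain <- mseOf(trIdx, params)
  trainLoss <- numeric(0); valLoss <- numeric(0)
  sinceBest <- 0
  if (config$epochs > 0) {
    for (e in seq_len(config$epochs)) {
      ord <- withSeed(childSeed(config$seed, "epoch", e),
                      sample(trIdx))
      bs <- config$batchSize
      epochLoss <- 0; nb <- 0
      for (start in seq(1, length(ord), by = bs)) {
        b <- ord[start:min(start + bs - 1, length(ord))]
        fw <- .nnForward(xN[b, , drop = FALSE], params, spec)
        resid <- fw$pred - yN[b, , drop = FALSE]
        loss <- mean(resid^2)
        if (!is.finite(loss))
          stop("trainModel: divergence (NaN loss); config: lr = ",
               config$lr, ", decay = ", config$decay, ", batch = ",
               config$batchSize)
        epochLoss <- epochLoss + loss; nb <- nb + 1
        g <- .nnBackward(2 * resid / length(resid), params, spec,
                         fw$caches)
        up <- .rmspropStep(params, g, state, config$lr, config$decay)
        params <- up$params; state <- up$state
      }
      trainLoss <- c(trainLoss, epochLoss / nb)
      if (length(valIdx)) {
        vl <- mseOf(valIdx, params)
        valLoss <- c(valLoss, vl)
        if (vl < bestVal) {
          bestVal <- vl; best <- params; sinceBest <- 0
        } else {
          sinceBest <- sinceBest + 1
          if (sinceBest >= config$patience) break
        }
      } else {
        best <- params
      }
    }
  }
  if (!length(valIdx) || config$epochs == 0) best <- if (config$epochs == 0)
    model@params else best
  finalTrain <- mseOf(trIdx, best)
  new("TrainedModel", spec = spec, params = best, norm = norm,
      log = list(trained = config$epochs > 0, trainLoss = trainLoss,
                 valLoss = valLoss, bestValLoss = bestVal,
                 initialTrainLoss = initialTrain,
                 finalTrainLoss = finalTrain),
      provenance = list(initSeed = model@provenance$initSeed,
                        trainSeed = config$seed,
                        config = unclass(config),
                        dataHash = .dataHash(x, y),
                        package = as.character(
                          utils::packageVersion("micral"))))
}

.checkGrid <- function(model, wn) {
  ref <- model@norm$wavenumbers
  if (is.null(ref))
    stop("model has no normalization statistics (untrained?)")
  if (length(ref) != length(wn) || max(abs(ref - wn)) > 1e-6)
    stop("grid mismatch: model was trained on a different wavenumber grid")
}

# Predict on a raw (unnormalized) input matrix, denormalized output.
.predictMatrix <- function(model, X, batch = 256L) {
  spec <- model@spec
  xN <- .normalizeX(X, model@norm)
  out <- NULL
  for (start in seq(1, nrow(X), by = batch)) {
    b <- start:min(start + batch - 1, nrow(X))
    p <- .nnForward(xN[b, , drop = FALSE], model@params, spec)$pred
    out <- rbind(out, p)
  }
  if (spec$task == "transfer")
    out * model@norm$yScale + model@norm$yMin
  else
    sweep(sweep(out, 2, model@norm$ySd, "*"), 2, model@norm$yMean, "+")
}

#' Apply a transfer model to a hyperspectral cube
#'
#' Maps every valid pixel spectrum independently into the bulk-spectrum
#' domain; the mask is preserved and invalid pixels are passed through as
#' zeros. The output lives on the model's (and cube's) grid.
#'
#' @param model a trained transfer [TrainedModel-class].
#' @param cube a [HyperspectralCube-class] on the model's grid.
#' @return a [HyperspectralCube-class] of transferred spectra.
#' @export
applyTransfer <- function(model, cube) {
  if (model@spec$task != "transfer")
    stop("applyTransfer: not a transfer model")
  .checkGrid(model, cube@grid@values)
  d <- dim(cube@data)
  M <- matrix(cube@data, d[1] * d[2], d[3])
  valid <- as.vector(cube@mask)
  out <- matrix(0, nrow(M), ncol(M))
  if (any(valid))
    out[valid, ] <- .predictMatrix(model, M[valid, , drop = FALSE])
  res <- cube
  res@data <- array(out, d)
  mt <- res@meta
  mt$transferred <- TRUE
  res@meta <- mt
  res
}

#' Predict analyte values
#'
#' Applies a calibration model to a spectrum, a matrix of spectra (rows) or
#' a hyperspectral cube; outputs are on the analyte's native scale
#' (denormalized). For cubes, an H x W value map is returned with invalid
#' pixels set to `NA`.
#'
#' @param model a trained calibration [TrainedModel-class].
#' @param x a [Spectrum-class], numeric matrix, or
#'   [HyperspectralCube-class].
#' @return numeric value(s) or an H x W matrix for cubes.
#' @export
predictValue <- function(model, x) {
  if (model@spec$task != "calibration")
    stop("predictValue: not a calibration model")
  if (is(x, "Spectrum")) {
    .checkGrid(model, wavenumbers(x))
    return(as.numeric(.predictMatrix(model, matrix(absorbance(x), 1))))
  }
  if (is(x, "HyperspectralCube")) {
    .checkGrid(model, x@grid@values)
    d <- dim(x@data)
    M <- matrix(x@data, d[1] * d[2], d[3])
    valid <- as.vector(x@mask)
    v <- rep(NA_real_, nrow(M))
    if (any(valid))
      v[valid] <- .predictMatrix(model, M[valid, , drop = FALSE])[, 1]
    return(matrix(v, d[1], d[2]))
  }
  if (is.matrix(x)) {
    if (ncol(x) != model@spec$inputLength)
      stop("grid mismatch: input length differs from model grid")
    return(.predictMatrix(model, x))
  }
  stop("predictValue: unsupported input type")
}

#' Save a model to a single file
#'
#' Serializes the architecture spec, parameters, normalization statistics,
#' training log and provenance with a mandatory format-version field.
#'
#' @param model a [TrainedModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(container = "micral-model", version = 1L,
               spec = model@spec, params = model@params,
               norm = model@norm, log = model@log,
               provenance = model@provenance), path)
  invisible(path)
}

#' Load a model saved by [saveModel()]
#'
#' @param path model file path.
#' @return a [TrainedModel-class]; predictions round-trip bit-exactly.
#' @export
loadModel <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("loadModel: cannot read model file (", conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$container, "micral-model"))
    stop("loadModel: not a model file")
  if (!identical(obj$version, 1L))
    stop("loadModel: unsupported model version ", obj$version)
  new("TrainedModel", spec = obj$spec, params = obj$params,
      norm = obj$norm, log = obj$log, provenance = obj$provenance)
}
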