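# Shared fixtures, memoized across test files so expensive objects are built
# at most once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# Small grid + band library used by most module tests.
smallGrid <- function() fixture("smallGrid", function() syntheticGrid(64))

smallLib <- function() fixture("smallLib", function() generateBandLibrary(3))

# A tiny dataset (fast): 4 samples, 8x8 tiles, small intact scene.
tinyDataset <- function() fixture("tinyDataset", function() {
  cfg <- datasetConfig(grid = syntheticGrid(64),
                       tile = tileConfig(size = 8),
                       scene = sceneSpec(height = 16, width = 16,
                                         nDroplets = 2, nHyphae = 1,
                                         dropletRadiusPx = c(1.5, 3)),
                       nReplicates = 2)
  generateDataset(4, cfg, seed = 42)
})

# ---- Acceptance-scale fixture (12 samples, 32x32 tiles, 200-point grid) ----
# Built lazily; every acceptance block that needs the trained models shares
# the same objects, so the expensive training happens once.

accDataset <- function() fixture("accDataset", function()
  generateDataset(12, datasetConfig(), seed = 11))

accPairs <- function() fixture("accPairs", function()
  buildTransferPairs(accDataset(), nPixelsPerSample = 16, seed = 5))

accTransferModel <- function() fixture("accTransferModel", function() {
  spec <- networkSpec(length(wavenumbers(accDataset()$grid)), "transfer")
  t0 <- proc.time()[3]
  m <- trainModel(buildModel(spec, 4), accPairs(),
                  trainConfig(epochs = 100, patience = 25, seed = 3))
  attr(m, "trainSeconds") <- proc.time()[3] - t0
  m
})

accLoo <- function() fixture("accLoo", function() {
  t0 <- proc.time()[3]
  loo <- looCrossValidate(accDataset(), analyte = "total_lipid",
                          transferModel = accTransferModel(), seed = 21)
  loo$seconds <- proc.time()[3] - t0
  loo
})

# Calibration model trained on the full acceptance dataset (for the
# intact-scene block, where no sample is held out).
accCalibrationModel <- function() fixture("accCalibrationModel", function() {
  ds <- accDataset()
  K <- length(wavenumbers(ds$grid))
  calSet <- buildCalibrationSet(micral:::.bulkTargets(ds), ds$reference,
                                "total_lipid", includeZeroFraction = 0.25,
                                seed = 7, nAugment = 5)
  spec <- networkSpec(K, "calibration", channels = c(8, 8), kernels = c(9, 7),
                      attnHeads = 2, attnDim = 4, hidden = 16)
  cal <- trainModel(buildModel(spec, 11), calSet,
                    trainConfig(lr = 2e-3, epochs = 120, batchSize = 8,
                                valFraction = 0, seed = 13))
  cal@provenance$analyte <- "total_lipid"
  cal
})
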