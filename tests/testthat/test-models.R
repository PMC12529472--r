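# Network specification, analytic gradients, training behavior, persistence
# and deterministic inference of the attention-augmented 1-D CNN.

# A tiny synthetic regression problem shared by the training tests.
tinyPairs <- function(task, n = 24, K = 32, seed = 2) {
  micral:::withSeed(seed, {
    g <- WavenumberGrid(seq(1000, 1800, length.out = K))
    x <- matrix(stats::runif(n * K), n, K)
    if (task == "transfer")
      structure(list(x = x, y = 0.5 * x + 0.1, grid = g,
                     sampleId = rep("A", n), task = "transfer"),
                class = "TrainingSet")
    else
      structure(list(x = x, y = rowMeans(x) * 50, grid = g,
                     sampleId = rep("A", n), analyte = "total_lipid",
                     task = "calibration"),
                class = "TrainingSet")
  })
}

test_that("network specification is validated", {
  expect_error(networkSpec(100, "transfer", channels = c(8, 16),
                           kernels = c(9, 7, 5)), "equal length")
  expect_error(networkSpec(100, "transfer", kernels = c(8, 7, 5)), "odd")
  expect_error(networkSpec(0, "transfer"), "positive")
})

test_that("the default transfer network stays small", {
  spec <- networkSpec(200, "transfer")
  m <- buildModel(spec, 1)
  expect_lt(nParameters(m), 200000)
  expect_gt(nParameters(m), 100)
})

test_that("analytic gradients match finite differences for both heads", {
  for (task in c("transfer", "calibration")) {
    spec <- networkSpec(20, task, channels = c(3, 4), kernels = c(5, 3),
                        attnHeads = 2, attnDim = 3, hidden = 6)
    p <- micral:::.nnInit(spec, 7)
    micral:::withSeed(4, {
      X <- matrix(stats::rnorm(4 * 20), 4, 20)
      Y <- if (task == "transfer") matrix(stats::rnorm(4 * 20), 4, 20)
           else matrix(stats::rnorm(4), 4, 1)
    })
    o <- micral:::.nnForward(X, p, spec)
    g <- micral:::.nnBackward(2 * (o$pred - Y) / length(Y), p, spec,
                              o$caches)
    fwd <- function(pp) {
      oo <- micral:::.nnForward(X, pp, spec)
      mean((oo$pred - Y)^2)
    }
    worst <- 0
    for (nm in names(p)) {
      idx <- micral:::withSeed(9, sample(length(p[[nm]]),
                                         min(3, length(p[[nm]]))))
      for (i in idx) {
        eps <- 1e-5
        p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps; f1 <- fwd(p2)
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; f2 <- fwd(p2)
        num <- (f1 - f2) / (2 * eps)
        worst <- max(worst, abs(num - g[[nm]][i]) /
                       max(1e-8, abs(num) + abs(g[[nm]][i])))
      }
    }
    expect_lt(worst, 1e-4)
  }
})

test_that("the attention softmax stays finite for extreme activations", {
  spec <- networkSpec(16, "calibration", channels = c(3), kernels = c(5),
                      attnHeads = 1, attnDim = 3, hidden = 4)
  p <- micral:::.nnInit(spec, 2)
  X <- matrix(c(rep(1e4, 16), rep(-1e4, 16), stats::rnorm(16)), 3, 16,
              byrow = TRUE)
  o <- micral:::.nnForward(X, p, spec)
  expect_true(all(is.finite(o$pred)))
})

test_that("training reduces the loss and honors the task declaration", {
  pairs <- tinyPairs("transfer")
  spec <- networkSpec(32, "transfer", channels = c(4, 4), kernels = c(7, 5),
                      attnHeads = 1, attnDim = 4)
  m <- trainModel(buildModel(spec, 1), pairs,
                  trainConfig(epochs = 40, valFraction = 0, seed = 5))
  expect_lt(tail(m@log$trainLoss, 1), m@log$trainLoss[1] / 2)
  expect_true(m@log$trained)
  calPairs <- tinyPairs("calibration")
  expect_error(trainModel(buildModel(spec, 1), calPairs, trainConfig()),
               "task")
})

test_that("zero-epoch training keeps the initial parameters", {
  pairs <- tinyPairs("calibration")
  spec <- networkSpec(32, "calibration", channels = c(4), kernels = c(5),
                      attnHeads = 1, attnDim = 3, hidden = 4)
  m0 <- buildModel(spec, 3)
  m <- trainModel(m0, pairs, trainConfig(epochs = 0, valFraction = 0))
  expect_identical(m@params, m0@params)
  expect_false(m@log$trained)
})

test_that("training is deterministic for a fixed seed", {
  pairs <- tinyPairs("calibration")
  spec <- networkSpec(32, "calibration", channels = c(4), kernels = c(5),
                      attnHeads = 1, attnDim = 3, hidden = 4)
  cfg <- trainConfig(epochs = 10, valFraction = 0, seed = 8)
  m1 <- trainModel(buildModel(spec, 3), pairs, cfg)
  m2 <- trainModel(buildModel(spec, 3), pairs, cfg)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@log$trainLoss, m2@log$trainLoss)
})

test_that("normalization statistics come from the training data only", {
  pairs <- tinyPairs("calibration")
  spec <- networkSpec(32, "calibration", channels = c(4), kernels = c(5),
                      attnHeads = 1, attnDim = 3, hidden = 4)
  m <- trainModel(buildModel(spec, 3), pairs,
                  trainConfig(epochs = 1, valFraction = 0))
  expect_equal(m@norm$yMean, mean(pairs$y), tolerance = 1e-9)
  expect_equal(m@norm$xMean, colMeans(pairs$x), tolerance = 1e-9)
})

test_that("model save/load round-trip reproduces predictions exactly", {
  pairs <- tinyPairs("calibration")
  spec <- networkSpec(32, "calibration", channels = c(4), kernels = c(5),
                      attnHeads = 1, attnDim = 3, hidden = 4)
  m <- trainModel(buildModel(spec, 3), pairs,
                  trainConfig(epochs = 10, valFraction = 0))
  path <- file.path(tempdir(), "model.rds")
  saveModel(m, path)
  back <- loadModel(path)
  s <- Spectrum(pairs$grid@values, pairs$x[1, ])
  expect_identical(predictValue(back, s), predictValue(m, s))
  # corrupt and wrong-format files are rejected
  bad <- file.path(tempdir(), "bad.rds")
  saveRDS(list(a = 1), bad)
  expect_error(loadModel(bad), "not a model file")
  writeLines("garbage", bad)
  expect_error(loadModel(bad), "cannot read")
})

test_that("prediction is deterministic and grid-checked", {
  pairs <- tinyPairs("calibration")
  spec <- networkSpec(32, "calibration", channels = c(4), kernels = c(5),
                      attnHeads = 1, attnDim = 3, hidden = 4)
  m <- trainModel(buildModel(spec, 3), pairs,
                  trainConfig(epochs = 10, valFraction = 0))
  s <- Spectrum(pairs$grid@values, pairs$x[2, ])
  expect_identical(predictValue(m, s), predictValue(m, s))
  wrong <- Spectrum(seq(900, 1700, length.out = 32), pairs$x[2, ])
  expect_error(predictValue(m, wrong), "grid mismatch")
})

test_that("applyTransfer maps valid pixels and zeroes invalid ones", {
  pairs <- tinyPairs("transfer")
  spec <- networkSpec(32, "transfer", channels = c(4), kernels = c(5),
                      attnHeads = 1, attnDim = 3)
  m <- trainModel(buildModel(spec, 2), pairs,
                  trainConfig(epochs = 10, valFraction = 0))
  K <- 32
  mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2)
  cube <- HyperspectralCube(pairs$grid,
                            array(stats::runif(2 * 2 * K), c(2, 2, K)),
                            mask = mask)
  out <- applyTransfer(m, cube)
  expect_identical(cubeMask(out), mask)
  expect_true(all(cubeData(out)[2, 1, ] == 0))
  expect_gt(max(abs(cubeData(out)[1, 1, ])), 0)
  calPairs <- tinyPairs("calibration")
  cal <- trainModel(buildModel(networkSpec(32, "calibration",
                                           channels = c(4), kernels = c(5),
                                           attnHeads = 1, attnDim = 3,
                                           hidden = 4), 3),
                    calPairs, trainConfig(epochs = 5, valFraction = 0))
  expect_error(applyTransfer(cal, cube), "not a transfer model")
  # calibration on a cube: NA outside the mask
  v <- predictValue(cal, cube)
  expect_true(is.na(v[2, 1]))
  expect_false(is.na(v[1, 1]))
})
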