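# Band library, Beer-Lambert mixtures, instrument responses, homogenized
# tiles, intact scenes and the full seeded dataset generator.

test_that("band library is a pure function of the seed with bounded jitter", {
  l1 <- generateBandLibrary(5)
  l2 <- generateBandLibrary(5)
  l3 <- generateBandLibrary(6)
  expect_identical(l1, l2)
  expect_false(identical(unclass(l1), unclass(l3)))
  anchors <- micral:::.anchorBands()
  for (comp in names(anchors)) {
    expect_true(all(abs(l1[[comp]]$center - anchors[[comp]]$center) <= 3))
    expect_true(all(l1[[comp]]$height / anchors[[comp]]$height >= 0.85 - 1e-9))
    expect_true(all(l1[[comp]]$height / anchors[[comp]]$height <= 1.15 + 1e-9))
  }
  # lipid ester carbonyl stays near 1745 cm^-1
  expect_true(any(abs(l1$lipid_sat$center - 1745) <= 10))
})

test_that("mixture spectra obey Beer-Lambert linearity", {
  lib <- smallLib()
  g <- smallGrid()
  c1 <- compositionVector(c(protein = 1), requireSum = FALSE)
  c2 <- compositionVector(c(carbohydrate = 1), requireSum = FALSE)
  a1 <- absorbance(mixtureSpectrum(c1, lib, 1, g))
  a2 <- absorbance(mixtureSpectrum(c2, lib, 1, g))
  mixed <- absorbance(mixtureSpectrum(0.3 * c1 + 0.7 * c2, lib, 1, g))
  expect_equal(mixed, 0.3 * a1 + 0.7 * a2, tolerance = 1e-12)
  # pathlength scales absorbance linearly
  doubled <- absorbance(mixtureSpectrum(c1, lib, 2, g))
  expect_equal(doubled, 2 * a1, tolerance = 1e-12)
})

test_that("composition vectors are validated and completed", {
  v <- compositionVector(c(lipid_sat = 0.2, lipid_unsat = 0.1,
                           protein = 0.4, carbohydrate = 0.25,
                           chitin = 0.05))
  expect_named(v, c("lipid_sat", "lipid_unsat", "protein", "carbohydrate",
                    "chitin"))
  expect_error(compositionVector(c(gold = 1), requireSum = FALSE), "unknown")
  expect_error(compositionVector(c(protein = 0.4)), "sum to 1")
  expect_error(compositionVector(c(protein = -0.1), requireSum = FALSE),
               ">= 0")
})

test_that("analytes derive from the composition as documented", {
  an <- analytesFromComposition(c(lipid_sat = 0.3, lipid_unsat = 0.1,
                                  protein = 0.35, carbohydrate = 0.2,
                                  chitin = 0.05))
  expect_equal(unname(an["total_lipid"]), 40)
  expect_equal(unname(an["SFA"]), 75)      # share of total fatty acids
  expect_equal(unname(an["PFA"]), 25)
  expect_equal(unname(an["GlcN"]), 5)
  expect_equal(unname(an["SFA"] + an["PFA"]), 100)
})

test_that("instrument response broadens bands and adds calibrated noise", {
  lib <- smallLib()
  g <- WavenumberGrid(seq(1500, 1800, length.out = 301))
  clean <- mixtureSpectrum(c(protein = 1), lib, 1, g)
  noiseless <- applyInstrument(clean, "micro",
                               config = instrumentConfig("micro", gainSd = 0,
                                                         baselineAmp = 0,
                                                         noiseSd = 0))
  # convolution conserves roughly the band area but lowers the peak
  expect_lt(max(absorbance(noiseless)), max(absorbance(clean)))
  expect_equal(mean(absorbance(noiseless)), mean(absorbance(clean)),
               tolerance = 0.02)
  # residual standard deviation reflects the configured noise
  cfg <- instrumentConfig("micro", gainSd = 0, baselineAmp = 0,
                          noiseSd = 0.01)
  res <- vapply(1:20, function(i)
    stats::sd(absorbance(applyInstrument(clean, "micro", seed = i,
                                         config = cfg)) -
                absorbance(noiseless)), numeric(1))
  expect_equal(mean(res), 0.01, tolerance = 0.2)
  # deterministic per seed
  s1 <- applyInstrument(clean, "macro", seed = 4)
  s2 <- applyInstrument(clean, "macro", seed = 4)
  expect_identical(absorbance(s1), absorbance(s2))
})

test_that("homogenized tile pixel-mean composition equals the bulk composition", {
  lib <- smallLib()
  comp <- c(lipid_sat = 0.25, lipid_unsat = 0.15, protein = 0.3,
            carbohydrate = 0.2, chitin = 0.1)
  tile <- renderHomogenizedTile(comp, lib, smallGrid(),
                                tileConfig(size = 12), seed = 8)
  tr <- meta(tile)$truth
  normal <- tr$aberrantType == "normal"
  meanComp <- colMeans(tr$composition[as.vector(normal), ])
  expect_equal(unname(meanComp), unname(compositionVector(comp)),
               tolerance = 1e-10)
  expect_true(all(tr$composition >= 0))
  expect_equal(unname(rowSums(tr$composition)), rep(1, 144),
               tolerance = 1e-10)
})

test_that("aberrant tile pixels are labeled and physically distinct", {
  lib <- smallLib()
  comp <- c(lipid_sat = 0.2, lipid_unsat = 0.1, protein = 0.35,
            carbohydrate = 0.25, chitin = 0.1)
  tile <- renderHomogenizedTile(comp, lib, smallGrid(),
                                tileConfig(size = 16, aberrantFraction = 0.2),
                                seed = 9)
  tr <- meta(tile)$truth
  expect_gt(sum(tr$aberrantType == "empty"), 0)
  expect_gt(sum(tr$aberrantType == "cluster"), 0)
  # near-empty pixels have tiny pathlength; cluster pixels have high lipid
  expect_true(all(tr$pathlength[tr$aberrantType == "empty"] < 0.1))
  expect_true(all(tr$lipid[tr$aberrantType == "cluster"] > 80))
})

test_that("intact scenes contain droplets, hyphae and empty background", {
  ds <- tinyDataset()
  sc <- ds$samples[[1]]$intact
  lab <- sc$maps$labels
  expect_setequal(intersect(unique(as.vector(lab)),
                            c("droplet", "hypha", "background")),
                  unique(as.vector(lab)))
  expect_gt(sum(lab == "droplet"), 0)
  expect_gt(sum(lab == "background"), 0)
  # truth lipid: droplets are lipid-rich, background is zero
  tl <- sc$maps$total_lipid
  expect_gt(mean(tl[lab == "droplet"]), 70)
  expect_true(all(tl[lab == "background"] == 0))
  if (any(lab == "hypha")) {
    expect_lt(mean(tl[lab == "hypha"]), 50)
    expect_gt(mean(tl[lab == "droplet"]), mean(tl[lab == "hypha"]))
  }
  # pixel spectra of the scene carry scattering distortion: non-negative,
  # finite, on the dataset grid
  expect_identical(wavenumbers(sc$cube@grid), wavenumbers(ds$grid))
  expect_true(all(is.finite(cubeData(sc$cube))))
})

test_that("dataset generation is reproducible and spans the lipid range", {
  ds <- tinyDataset()
  expect_length(ds$samples, 4)
  ref <- ds$reference
  expect_silent(validateReferenceTable(ref))
  tl <- ref$value[ref$analyte == "total_lipid"]
  expect_true(all(tl >= 5 & tl <= 70))
  expect_length(ds$samples[[1]]$bulk, 2)
  # SFA + PFA = 100 for every sample
  for (s in ds$samples)
    expect_equal(unname(s$analytes["SFA"] + s$analytes["PFA"]), 100,
                 tolerance = 1e-9)
  # regenerating with the same seed gives identical numbers
  ds2 <- generateDataset(4, ds$config, seed = 42)
  expect_identical(cubeData(ds$samples[[2]]$homogenized),
                   cubeData(ds2$samples[[2]]$homogenized))
  expect_identical(absorbance(ds$samples[[3]]$bulk[[1]]),
                   absorbance(ds2$samples[[3]]$bulk[[1]]))
  expect_identical(ds$reference$value, ds2$reference$value)
})

test_that("stratified lipid draws cover the range more evenly than the extremes", {
  ds <- tinyDataset()
  tl <- sort(ds$reference$value[ds$reference$analyte == "total_lipid"])
  # one draw per stratum: successive values fall in disjoint quarters
  edges <- seq(5, 70, length.out = 5)
  expect_true(all(tl >= edges[-5] & tl <= edges[-1]))
})

test_that("exportDataset writes cubes, spectra, references and truth maps", {
  ds <- tinyDataset()
  dir <- file.path(tempdir(), "ds-export")
  exportDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "bulk_spectra.csv")))
  expect_true(file.exists(file.path(dir, "reference.csv")))
  expect_true(file.exists(file.path(dir, "S01_homogenized.hdr")))
  expect_true(file.exists(file.path(dir, "S01_intact.hdr")))
  expect_true(file.exists(file.path(dir, "S01_truth.json")))
  back <- readCube(file.path(dir, "S01_homogenized"))
  expect_equal(cubeData(back), cubeData(ds$samples[[1]]$homogenized),
               tolerance = 1e-12)
})
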