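# Wavenumber grids, Spectrum/cube containers, resampling, trimming, seeded
# RNG helpers and the text-based I/O round-trips.

test_that("wavenumber grids must be ascending, positive and long enough", {
  expect_s4_class(WavenumberGrid(seq(900, 1800, by = 10)), "WavenumberGrid")
  expect_error(WavenumberGrid(c(seq(1000, 1008), 1005)), "increasing")
  expect_error(WavenumberGrid(seq(-5, 175, by = 20)), "positive")
  expect_error(WavenumberGrid(c(900, 1000)), "at least")
})

test_that("Spectrum canonicalizes a descending grid by reversing both axes", {
  v <- seq(1800, 900, by = -100)
  a <- seq_along(v) / 10
  s <- Spectrum(v, a)
  expect_equal(wavenumbers(s), rev(v))
  expect_equal(absorbance(s), rev(a))
  # ascending input is untouched
  s2 <- Spectrum(rev(v), rev(a))
  expect_equal(absorbance(s2), absorbance(s))
})

test_that("Spectrum validity rejects length mismatch and non-finite values", {
  v <- seq(900, 1800, by = 100)
  expect_error(Spectrum(v, numeric(3)))
  expect_error(Spectrum(v, c(rep(1, length(v) - 1), NA)))
})

test_that("cube dimensions, mask shape and accessors are consistent", {
  g <- smallGrid()
  K <- length(wavenumbers(g))
  arr <- array(runif(4 * 5 * K), c(4, 5, K))
  cube <- HyperspectralCube(g, arr)
  expect_identical(dim(cubeData(cube)), c(4L, 5L, K))
  expect_true(all(cubeMask(cube)))
  expect_error(HyperspectralCube(g, arr, mask = matrix(TRUE, 3, 5)))
  expect_error(HyperspectralCube(g, array(1, c(4, 5, K + 1))))
})

test_that("linear resampling is exact for affine spectra and refuses to extrapolate", {
  g1 <- WavenumberGrid(seq(1000, 2000, by = 25))
  s <- Spectrum(g1@values, 0.3 + 0.001 * g1@values)
  g2 <- WavenumberGrid(seq(1010, 1990, by = 7))
  r <- resampleToGrid(s, g2)
  expect_equal(absorbance(r), 0.3 + 0.001 * g2@values, tolerance = 1e-12)
  expect_error(resampleToGrid(s, WavenumberGrid(seq(900, 1500, by = 10))),
               "range")
})

test_that("trimRange keeps exactly the in-window points on spectra and cubes", {
  g <- WavenumberGrid(seq(1000, 2000, by = 50))
  s <- Spectrum(g@values, seq_along(g@values) / 10)
  t1 <- trimRange(s, 1200, 1600)
  expect_true(all(wavenumbers(t1) >= 1200 & wavenumbers(t1) <= 1600))
  expect_equal(length(wavenumbers(t1)), sum(g@values >= 1200 & g@values <= 1600))
  K <- length(g@values)
  cube <- HyperspectralCube(g, array(rep(seq_len(K), each = 6), c(2, 3, K)))
  t2 <- trimRange(cube, 1200, 1600)
  expect_equal(length(wavenumbers(t2@grid)), length(wavenumbers(t1)))
  expect_error(trimRange(s, 1600, 1200), "lo must be")
  expect_error(trimRange(s, 2500, 2600), "no grid points")
})

test_that("withSeed restores the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  a <- micral:::withSeed(9, runif(3))
  expect_identical(.Random.seed, before)
  b <- micral:::withSeed(9, runif(3))
  expect_identical(a, b)
  c2 <- micral:::withSeed(10, runif(3))
  expect_false(identical(a, c2))
})

test_that("childSeed is deterministic, tag-sensitive and below 2^31", {
  s1 <- micral:::childSeed(7, "a", 1)
  expect_identical(s1, micral:::childSeed(7, "a", 1))
  expect_false(s1 == micral:::childSeed(7, "a", 2))
  expect_false(s1 == micral:::childSeed(8, "a", 1))
  seeds <- vapply(1:200, function(i) micral:::childSeed(i, "x", i),
                  integer(1))
  expect_true(all(seeds >= 1 & seeds < 2^31))
})

test_that("ENVI cube round-trip preserves data, grid, mask and metadata", {
  g <- smallGrid()
  K <- length(wavenumbers(g))
  arr <- array(rnorm(3 * 4 * K), c(3, 4, K))
  mask <- matrix(c(TRUE, FALSE), 3, 4)
  cube <- HyperspectralCube(g, arr, mask = mask, sample_id = "T1")
  path <- file.path(tempdir(), "t1")
  writeCube(cube, path, format = "envi")
  back <- readCube(path)
  expect_equal(cubeData(back), arr, tolerance = 1e-12)
  expect_equal(wavenumbers(back@grid), wavenumbers(g))
  expect_identical(cubeMask(back), mask)
  expect_identical(meta(back)$sample_id, "T1")
})

test_that("JSON cube round-trip preserves data, grid and mask", {
  g <- smallGrid()
  K <- length(wavenumbers(g))
  arr <- array(rnorm(2 * 2 * K), c(2, 2, K))
  cube <- HyperspectralCube(g, arr, mask = matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2))
  path <- file.path(tempdir(), "t2.json")
  writeCube(cube, path, format = "json")
  back <- readCube(path)
  expect_equal(cubeData(back), arr, tolerance = 1e-9)
  expect_identical(cubeMask(back), cubeMask(cube))
})

test_that("readCube rejects missing and malformed inputs", {
  expect_error(readCube(file.path(tempdir(), "nope-xyz")), "no such file")
  bad <- file.path(tempdir(), "bad.json")
  writeLines('{"format": "something-else"}', bad)
  expect_error(readCube(bad), "not a micral cube")
})

test_that("spectra table round-trip preserves grids, values and ids", {
  g <- smallGrid()
  sp <- list(Spectrum(g@values, runif(length(g@values)), sample_id = "A",
                      replicate = 1L, instrument = "macro"),
             Spectrum(g@values, runif(length(g@values)), sample_id = "B",
                      replicate = 2L, instrument = "macro"))
  path <- file.path(tempdir(), "spectra.csv")
  writeSpectraTable(sp, path)
  back <- readSpectraTable(path)
  expect_length(back, 2)
  expect_equal(absorbance(back[[1]]), absorbance(sp[[1]]), tolerance = 1e-9)
  expect_identical(meta(back[[2]])$sample_id, "B")
  expect_equal(wavenumbers(back[[1]]), g@values, tolerance = 1e-9)
})

test_that("reference tables are validated for range and duplicate keys", {
  df <- data.frame(sample_id = c("A", "A", "B"),
                   analyte = c("total_lipid", "SFA", "total_lipid"),
                   value = c(30, 55, 10), replicate = 1L)
  expect_silent(validateReferenceTable(df))
  bad <- df; bad$value[1] <- 150
  expect_error(validateReferenceTable(bad), "\\[0, 100\\]")
  dup <- rbind(df, df[1, ])
  expect_error(validateReferenceTable(dup), "duplicate")
  path <- file.path(tempdir(), "ref.csv")
  writeReferenceTable(df, path)
  back <- readReferenceTable(path)
  expect_equal(back$value, df$value)
})
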