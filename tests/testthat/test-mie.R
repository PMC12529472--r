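# Lorenz-Mie series, aperture-restricted scattering efficiency,
# Kramers-Kronig transform and the apparent-absorbance forward model.
# Expected efficiencies were computed with an independent arbitrary-precision
# implementation (40 significant digits) and frozen here.

mieOracle <- list(
  list(x = 0.5, m = 1.33 + 0i,
       qSca = 0.00677313988383809822729, qExt = 0.00677313988383809822729),
  list(x = 0.5, m = 1.5 + 0.01i,
       qSca = 0.0145599230373159372767, qExt = 0.025865180905990172431),
  list(x = 1, m = 1.33 + 0i,
       qSca = 0.093924001214071766872, qExt = 0.093924001214071766872),
  list(x = 1, m = 1.5 + 0i,
       qSca = 0.21509759604288530594, qExt = 0.21509759604288530594),
  list(x = 1, m = 1.5 + 0.01i,
       qSca = 0.21363857159908760563, qExt = 0.24247933549977179925),
  list(x = 5, m = 1.33 + 0i,
       qSca = 3.5910329236295622534, qExt = 3.5910329236295622534),
  list(x = 5, m = 1.5 + 0.01i,
       qSca = 3.55435461613978618487, qExt = 3.81831877859533531879),
  list(x = 20, m = 1.33 + 0i,
       qSca = 2.14010715242744846287, qExt = 2.14010715242744846287),
  list(x = 20, m = 1.5 + 0.01i,
       qSca = 1.51081322912196336644, qExt = 2.11341716954901003437))

test_that("Mie efficiencies match frozen arbitrary-precision values", {
  for (o in mieOracle) {
    q <- mieEfficiencies(o$x, o$m)
    expect_equal(q$qSca, o$qSca, tolerance = 1e-12)
    expect_equal(q$qExt, o$qExt, tolerance = 1e-12)
    # qAbs is a difference of O(1) quantities: allow for the cancellation
    expect_equal(q$qAbs, o$qExt - o$qSca, tolerance = 1e-10)
  }
})

test_that("size parameter is 2 pi r nu in consistent units", {
  # r = 1 um, nu = 1000 cm^-1  ->  x = 2 pi * 1e-4 cm * 1000 cm^-1
  expect_equal(sizeParameter(1, 1000), 2 * pi * 0.1, tolerance = 1e-12)
  expect_equal(sizeParameter(5, c(1000, 2000)),
               2 * pi * 5e-4 * c(1000, 2000), tolerance = 1e-12)
})

test_that("a vacuum sphere (m = 1) does not scatter", {
  ab <- mieCoefficients(3, 1 + 0i)
  expect_lt(max(abs(ab$a)), 1e-12)
  expect_lt(max(abs(ab$b)), 1e-12)
})

test_that("small-particle limit reproduces the Rayleigh cross-section", {
  x <- 0.01; m <- 1.5
  rayleigh <- (8 / 3) * x^4 * abs((m^2 - 1) / (m^2 + 2))^2
  q <- mieEfficiencies(x, m + 0i)
  expect_equal(q$qSca, rayleigh, tolerance = 0.01)
})

test_that("large-particle extinction approaches the extinction paradox value 2", {
  q <- mieEfficiencies(200, 1.5 + 1e-4i)
  expect_gt(q$qExt, 1.8)
  expect_lt(q$qExt, 2.2)
})

test_that("optical theorem: series Q_ext equals the forward-amplitude form", {
  for (x in c(1, 5, 20)) {
    m <- 1.5 + 0.01i
    ab <- mieCoefficients(x, m)
    n <- seq_along(ab$a)
    # S(0) = 1/2 sum (2n+1)(a_n + b_n); Q_ext = 4/x^2 Re S(0)
    s0 <- 0.5 * sum((2 * n + 1) * (ab$a + ab$b))
    expect_equal(4 / x^2 * Re(s0), mieEfficiencies(x, m)$qExt,
                 tolerance = 1e-8)
  }
})

test_that("energy bookkeeping: qAbs = qExt - qSca >= 0 for absorbing spheres", {
  for (x in c(0.5, 1, 5, 20)) {
    q <- mieEfficiencies(x, 1.5 + 0.01i)
    expect_equal(q$qExt - q$qAbs - q$qSca, 0, tolerance = 1e-12)
    expect_gt(q$qAbs, 0)
  }
})

test_that("angular integral at zero aperture equals the series Q_sca", {
  for (x in c(0.5, 1, 5, 20)) {
    for (m in c(1.33 + 0i, 1.5 + 0.01i)) {
      expect_equal(qScaNA(x, m, thetaNA = 0), mieEfficiencies(x, m)$qSca,
                   tolerance = 1e-6)
    }
  }
})

test_that("aperture-restricted scattering decreases with aperture angle", {
  x <- 5; m <- 1.4 + 0.005i
  qs <- vapply(c(0, 0.1, 0.3, 0.6), function(th) qScaNA(x, m, th),
               numeric(1))
  expect_true(all(diff(qs) < 0))
  expect_true(all(qs > 0))
})

test_that("Mie domain guard rejects unstable size parameters", {
  expect_error(mieEfficiencies(600, 1.5 + 0i), "500")
})

test_that("Kramers-Kronig reproduces the dispersive Lorentzian partner", {
  nu <- seq(900, 3845, length.out = 1024)
  nu0 <- 2000; g <- 80; h <- 0.01
  nI <- h * g^2 / ((nu - nu0)^2 + g^2)
  expected <- h * g * (nu0 - nu) / ((nu - nu0)^2 + g^2)
  got <- kramersKronig(nI, WavenumberGrid(nu))
  interior <- seq(round(0.1 * 1024), round(0.9 * 1024))
  err <- max(abs(got[interior] - (expected[interior] -
                                    mean(expected[interior]) +
                                    mean(got[interior]))))
  expect_lt(err / max(abs(expected)), 0.02)
})

test_that("Kramers-Kronig of zero absorption is exactly zero", {
  nu <- seq(1000, 2000, length.out = 64)
  expect_identical(kramersKronig(numeric(64), WavenumberGrid(nu)),
                   numeric(64))
})

test_that("apparent absorbance spot values follow -log10(1 - f Q)", {
  # f Q = 0.5 -> A = 0.30103; f Q = 0.9 -> A = 1; Q = 0 -> A = 0 exactly
  expect_equal(apparentAbsorbance(0.5, 1), 0.30103, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(apparentAbsorbance(1.8, 0.5), 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(as.numeric(apparentAbsorbance(0, 0.7)), 0)
})

test_that("apparent absorbance clips saturated pixels and flags them", {
  a <- apparentAbsorbance(c(0.5, 2.5), 1)
  expect_true(attr(a, "saturated"))
  expect_true(all(is.finite(a)))
  expect_error(apparentAbsorbance(2.5, 1, onSaturate = "error"), "saturat")
})

test_that("efficiency curves decompose extinction into weighted absorption plus scattering", {
  g <- smallGrid()
  nu <- wavenumbers(g)
  nI <- 0.02 * exp(-((nu - 1650) / 60)^2)
  nm <- refractiveIndexModel(g, n0 = 1.4, nI = nI)
  geo <- MieGeometry(4, thetaNA = 0.1, fillFactor = 0.5, cAbs = 1.2)
  ec <- efficiencyCurves(nm, geo)
  expect_equal(ec$q_ext_na, 1.2 * ec$q_abs + ec$q_sca_na, tolerance = 1e-12)
  expect_equal(ec$q_ext_total - ec$q_sca_total, ec$q_abs, tolerance = 1e-10)
  # Q_abs = Q_ext - Q_sca may round to tiny negatives where n_i ~ 0
  expect_true(all(ec$q_abs >= -1e-10))
  expect_gt(max(ec$q_abs), 0)
})

test_that("distortSpectrum adds ripple, preserves the grid and flags its output", {
  g <- smallGrid()
  nu <- wavenumbers(g)
  clean <- Spectrum(nu, 0.4 * exp(-((nu - 1650) / 50)^2) +
                      0.2 * exp(-((nu - 2900) / 80)^2))
  geo <- MieGeometry(5, thetaNA = 0.1, fillFactor = 0.5)
  d <- distortSpectrum(clean, geo)
  expect_s4_class(d, "Spectrum")
  expect_identical(wavenumbers(d), nu)
  expect_true(all(absorbance(d) >= 0))
  expect_true(isTRUE(meta(d)$distorted))
  # the scattering ripple makes the distorted spectrum differ from a pure
  # rescaling of the clean one
  r <- stats::cor(absorbance(d), absorbance(clean))
  expect_lt(r, 0.999)
  expect_error(distortSpectrum(Spectrum(nu, rep(-0.1, length(nu))), geo),
               ">= 0")
})

test_that("a larger sphere radius shifts scattering power at fixed wavenumber", {
  # the Mie ripple is radius-dependent: two radii give different curves
  g <- smallGrid()
  nu <- wavenumbers(g)
  nm <- refractiveIndexModel(g, 1.4, nI = rep(0.005, length(nu)))
  e1 <- efficiencyCurves(nm, MieGeometry(3))
  e2 <- efficiencyCurves(nm, MieGeometry(9))
  expect_gt(max(abs(e1$q_ext_na - e2$q_ext_na)), 0.05)
})
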