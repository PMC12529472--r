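# Seeded synthetic-data generator: Beer-Lambert mixture spectra of fungal
# biomass components, paired macro/micro instrument responses, homogenized
# image tiles whose pixel-mean composition equals the bulk composition, and
# intact scenes (lipid droplets + hyphae) with Mie-distorted pixel spectra.

.components <- c("lipid_sat", "lipid_unsat", "protein", "carbohydrate",
                 "chitin")

# Anchor bands per component: center (cm^-1), half-width at half max
# (cm^-1), height (AU per unit concentration and pathlength), shape.
.anchorBands <- function() {
  bl <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(center = as.numeric(m[, 1]), width = as.numeric(m[, 2]),
               height = as.numeric(m[, 3]), shape = m[, 4],
               stringsAsFactors = FALSE)
  }
  list(
    lipid_sat = bl(
      2920, 18, 1.00, "lorentzian",
      2850, 15, 0.70, "lorentzian",
      1745, 12, 0.90, "lorentzian",
      1465, 12, 0.35, "gaussian",
      1170, 20, 0.30, "gaussian"),
    lipid_unsat = bl(
      3010, 12, 0.40, "lorentzian",
      2927, 18, 0.95, "lorentzian",
      2856, 15, 0.60, "lorentzian",
      1742, 13, 0.85, "lorentzian",
      1460, 12, 0.28, "gaussian"),
    protein = bl(
      3290, 60, 0.50, "gaussian",
      2960, 20, 0.15, "gaussian",
      1650, 25, 1.00, "lorentzian",
      1545, 25, 0.70, "lorentzian",
      1240, 25, 0.20, "gaussian"),
    carbohydrate = bl(
      3350, 90, 0.35, "gaussian",
      2900, 30, 0.20, "gaussian",
      1150, 25, 0.50, "lorentzian",
      1040, 30, 1.00, "lorentzian",
      990, 25, 0.40, "gaussian"),
    chitin = bl(
      3270, 70, 0.40, "gaussian",
      2880, 25, 0.20, "gaussian",
      1655, 25, 0.55, "lorentzian",
      1560, 25, 0.50, "lorentzian",
      1315, 20, 0.30, "gaussian",
      1075, 25, 0.80, "lorentzian"))
}

#' Generate a randomized band library
#'
#' Stands in for the molar absorption coefficients of the biomass
#' components (saturated and polyunsaturated lipid, protein, carbohydrate,
#' chitin/glucosamine): anchor bands at textbook mid-IR positions with
#' seeded jitter of centers (+-3 cm^-1), heights and widths (+-15%). The
#' lipid components keep an ester carbonyl band within 1745 +- 10 cm^-1.
#'
#' @param seed integer seed; the library is a pure function of it.
#' @return object of class `"BandLibrary"`: a named list of band
#'   data.frames (`center`, `width`, `height`, `shape`) plus a `seed`
#'   attribute.
#' @export
generateBandLibrary <- function(seed = 1) {
  anchors <- .anchorBands()
  lib <- withSeed(childSeed(seed, "bandlib"), {
    lapply(anchors, function(df) {
      df$center <- df$center + stats::runif(nrow(df), -3, 3)
      df$height <- df$height * stats::runif(nrow(df), 0.85, 1.15)
      df$width <- df$width * stats::runif(nrow(df), 0.85, 1.15)
      df
    })
  })
  structure(lib, class = "BandLibrary", seed = seed)
}

# Evaluate one component's bands on a wavenumber vector.
componentSpectrum <- function(bands, wn) {
  a <- numeric(length(wn))
  for (i in seq_len(nrow(bands))) {
    z <- (wn - bands$center[i]) / bands$width[i]
    a <- a + bands$height[i] *
      if (bands$shape[i] == "lorentzian") 1 / (1 + z^2)
      else exp(-log(2) * z^2)
  }
  a
}

# Component spectra matrix: one row per component, one column per grid point.
componentMatrix <- function(lib, grid) {
  wn <- if (is(grid, "WavenumberGrid")) grid@values else as.numeric(grid)
  t(vapply(.components, function(k) componentSpectrum(lib[[k]], wn),
           numeric(length(wn))))
}

#' Beer-Lambert mixture spectrum
#'
#' `A(nu) = l * sum_i C_i eps_i(nu)`: the scatter-free absorbance of a
#' mixture with mass fractions `comp` and optical pathlength `l`, using the
#' band library as the absorption coefficients.
#'
#' @param comp named numeric of non-negative mass fractions over
#'   `c("lipid_sat", "lipid_unsat", "protein", "carbohydrate", "chitin")`.
#' @param lib a `"BandLibrary"`.
#' @param pathlength optical-thickness multiplier `l` (default 1).
#' @param grid a [WavenumberGrid-class] or numeric wavenumbers.
#' @return a [Spectrum-class].
#' @export
mixtureSpectrum <- function(comp, lib, pathlength = 1, grid) {
  comp <- compositionVector(comp, requireSum = FALSE)
  E <- componentMatrix(lib, grid)
  Spectrum(if (is(grid, "WavenumberGrid")) grid@values else grid,
           pathlength * as.numeric(comp[.components] %*% E))
}

#' Validate / complete a composition vector
#'
#' @param comp named numeric of mass fractions (missing components are 0).
#' @param requireSum require the fractions to sum to 1 (default TRUE).
#' @return named numeric over all five components.
#' @export
compositionVector <- function(comp, requireSum = TRUE) {
  out <- stats::setNames(numeric(length(.components)), .components)
  if (!is.null(names(comp))) {
    bad <- setdiff(names(comp), .components)
    if (length(bad))
      stop("compositionVector: unknown components: ",
           paste(bad, collapse = ", "))
    out[names(comp)] <- comp
  } else {
    if (length(comp) != length(.components))
      stop("compositionVector: unnamed composition must have length 5")
    out[] <- comp
  }
  if (any(out < 0)) stop("compositionVector: fractions must be >= 0")
  if (requireSum && abs(sum(out) - 1) > 1e-8)
    stop("compositionVector: fractions must sum to 1")
  out
}

#' Derived analytes of a composition
#'
#' Total lipid as percent of biomass, SFA and PFA as percent of total fatty
#' acids, and glucosamine (the chitin fraction) as percent of biomass.
#'
#' @param comp composition vector (see [compositionVector()]).
#' @return named numeric: `total_lipid`, `SFA`, `PFA`, `GlcN` (percent).
#' @export
analytesFromComposition <- function(comp) {
  comp <- compositionVector(comp, requireSum = FALSE)
  fa <- comp["lipid_sat"] + comp["lipid_unsat"]
  c(total_lipid = unname(100 * fa),
    SFA = unname(if (fa > 0) 100 * comp["lipid_sat"] / fa else 0),
    PFA = unname(if (fa > 0) 100 * comp["lipid_unsat"] / fa else 0),
    GlcN = unname(100 * comp["chitin"]))
}

#' Instrument response configuration
#'
#' Lineshape and noise model of the two instruments: the macroscopic
#' HTS-FTIR (6 cm^-1 resolution, 1.928 cm^-1 digital spacing, resampled back
#' onto the working grid to emulate the interpolation of macroscopic
#' spectra) and the microscopic FPA system (8 cm^-1 resolution).
#'
#' @param which `"macro"` or `"micro"`.
#' @param fwhm lineshape full width at half maximum in cm^-1.
#' @param gainSd standard deviation of the log multiplicative gain.
#' @param baselineAmp maximum absolute baseline coefficient (AU).
#' @param baselineDegree polynomial baseline degree.
#' @param noiseSd additive white-noise standard deviation (AU).
#' @param macroSpacing digital spacing of the macroscopic instrument.
#' @return list of class `"InstrumentConfig"`.
#' @export
instrumentConfig <- function(which = c("macro", "micro"),
                             fwhm = NULL, gainSd = 0.02,
                             baselineAmp = NULL, baselineDegree = 2,
                             noiseSd = NULL, macroSpacing = 1.928) {
  which <- match.arg(which)
  if (is.null(fwhm)) fwhm <- if (which == "macro") 6 else 8
  if (is.null(baselineAmp)) baselineAmp <- if (which == "macro") 0.004
                            else 0.01
  if (is.null(noiseSd)) noiseSd <- if (which == "macro") 0.002 else 0.005
  structure(list(which = which, fwhm = fwhm, gainSd = gainSd,
                 baselineAmp = baselineAmp, baselineDegree = baselineDegree,
                 noiseSd = noiseSd, macroSpacing = macroSpacing),
            class = "InstrumentConfig")
}

# Gaussian lineshape convolution on an (even) grid, edge-renormalized.
.convolveLineshape <- function(M, wn, fwhm) {
  if (fwhm <= 0) return(M)
  sp <- stats::median(diff(wn))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  hw <- max(1L, ceiling(4 * sigma / sp))
  k <- stats::dnorm(seq(-hw, hw) * sp, sd = sigma)
  K <- ncol(M)
  pad <- matrix(0, nrow(M), hw)
  Mp <- cbind(pad, M, pad)
  out <- matrix(0, nrow(M), K)
  wsum <- numeric(K)
  ones <- c(rep(0, hw), rep(1, K), rep(0, hw))
  for (j in seq_along(k)) {
    out <- out + k[j] * Mp[, j:(j + K - 1), drop = FALSE]
    wsum <- wsum + k[j] * ones[j:(j + K - 1)]
  }
  sweep(out, 2, wsum, "/")
}

# Matrix form of the instrument response: rows are spectra on grid `wn`.
# Applies lineshape convolution, per-row gain, polynomial baseline and
# white noise; the macro variant goes through the macro digital spacing and
# back (linear interpolation both ways).
.instrumentMatrix <- function(M, wn, cfg, seed) {
  M <- .convolveLineshape(M, wn, cfg$fwhm)
  if (cfg$which == "macro" && cfg$macroSpacing > 0) {
    mg <- seq(min(wn), max(wn), by = cfg$macroSpacing)
    M <- t(apply(M, 1, function(r)
      stats::approx(mg, stats::approx(wn, r, xout = mg)$y, xout = wn,
                    rule = 2)$y))
  }
  n <- nrow(M); K <- ncol(M)
  withSeed(seed, {
    gain <- exp(stats::rnorm(n, 0, cfg$gainSd))
    tt <- seq(-1, 1, length.out = K)
    V <- t(vapply(0:cfg$baselineDegree, function(d) tt^d, numeric(K)))
    cf <- matrix(stats::runif(n * (cfg$baselineDegree + 1), -1, 1) *
                   cfg$baselineAmp, n)
    noise <- matrix(stats::rnorm(n * K, 0, cfg$noiseSd), n)
    M * gain + cf %*% V + noise
  })
}

#' Apply an instrument response to a spectrum
#'
#' Convolves with the instrument lineshape (macro 6 cm^-1 FWHM, micro
#' 8 cm^-1), applies a seeded multiplicative gain, a mild polynomial
#' baseline and additive white noise; macroscopic spectra additionally
#' round-trip through the macro digital spacing (1.928 cm^-1) to emulate
#' interpolation onto the microscopic grid.
#'
#' @param s a [Spectrum-class].
#' @param which `"macro"` or `"micro"` (ignored if `config` is given).
#' @param seed integer seed for gain/baseline/noise.
#' @param config an [instrumentConfig()]; defaults to the standard config
#'   of `which`.
#' @return a [Spectrum-class] on the same grid, with `instrument` recorded
#'   in its metadata.
#' @export
applyInstrument <- function(s, which = c("macro", "micro"), seed = 1,
                            config = NULL) {
  if (is.null(config)) config <- instrumentConfig(match.arg(which))
  wn <- wavenumbers(s)
  out <- .instrumentMatrix(matrix(absorbance(s), 1), wn, config, seed)
  mt <- s@meta
  mt$instrument <- config$which
  new("Spectrum", grid = s@grid, absorbance = as.numeric(out), meta = mt)
}

# Exact column re-centering of a nonnegative composition matrix: additive
# shift to the target means, then clamp negatives to zero per column and
# remove the clamped excess from the largest entries of that column.
# Column means equal `target` to machine precision; row sums stay within
# ~1e-3 of 1 (the deviation is absorbed by the pathlength factor).
recenterComposition <- function(C, target) {
  C <- sweep(C, 2, target - colMeans(C), "+")
  for (j in seq_len(ncol(C))) {
    neg <- C[, j] < 0
    if (!any(neg)) next
    excess <- -sum(C[neg, j])
    C[neg, j] <- 0
    pos <- which(!neg)
    w <- C[pos, j] / sum(C[pos, j])
    C[pos, j] <- C[pos, j] - excess * w
    # exact fix-up of any residual rounding
    C[pos[1], j] <- C[pos[1], j] - (mean(C[, j]) - target[j]) * nrow(C)
  }
  C
}

#' Homogenized-biomass tile configuration
#'
#' @param size tile side in pixels.
#' @param jitterKappa Dirichlet concentration of the per-pixel composition
#'   jitter (larger = more homogeneous).
#' @param pathSigma log-normal sigma of the per-pixel pathlength jitter
#'   (mean pathlength 1).
#' @param aberrantFraction expected fraction of aberrant pixels (near-empty
#'   or lipid-cluster), injected to exercise pixel quality control.
#' @param emptyPathlength pathlength of near-empty aberrant pixels.
#' @param clusterLipid lipid fraction of lipid-cluster aberrant pixels.
#' @return list of class `"TileConfig"`.
#' @export
tileConfig <- function(size = 32, jitterKappa = 300, pathSigma = 0.15,
                       aberrantFraction = 0.02, emptyPathlength = 0.02,
                       clusterLipid = 0.88) {
  structure(list(size = size, jitterKappa = jitterKappa,
                 pathSigma = pathSigma,
                 aberrantFraction = aberrantFraction,
                 emptyPathlength = emptyPathlength,
                 clusterLipid = clusterLipid), class = "TileConfig")
}

#' Render a homogenized-biomass hyperspectral tile
#'
#' Per-pixel composition jitter (Dirichlet around the bulk composition,
#' re-centered so the pixel-mean composition of the normal pixels equals the
#' bulk composition exactly) and log-normal pathlength jitter; a configurable
#' fraction of aberrant pixels (near-empty or lipid-cluster) is injected to
#' exercise quality control. Pixel spectra follow Beer-Lambert and the
#' microscopic instrument response.
#'
#' @param comp bulk composition (see [compositionVector()]).
#' @param lib a `"BandLibrary"`.
#' @param grid wavenumber grid.
#' @param config a [tileConfig()].
#' @param seed integer seed.
#' @param instrument micro [instrumentConfig()] (default standard).
#' @return a [HyperspectralCube-class]; `meta(x)$truth` holds the per-pixel
#'   ground truth (`lipid` map in percent, `composition` matrix, `aberrant`
#'   and `aberrantType` matrices, the bulk `analytes`).
#' @export
renderHomogenizedTile <- function(comp, lib, grid, config = tileConfig(),
                                  seed = 1, instrument = NULL) {
  comp <- compositionVector(comp)
  if (is.null(instrument)) instrument <- instrumentConfig("micro")
  n <- config$size^2
  wn <- if (is(grid, "WavenumberGrid")) grid@values else as.numeric(grid)
  st <- withSeed(childSeed(seed, "tile"), {
    aberrant <- stats::runif(n) < config$aberrantFraction
    abType <- ifelse(stats::runif(n) < 0.5, "empty", "cluster")
    abType[!aberrant] <- "normal"
    C <- if (config$jitterKappa > 0) {
      G <- matrix(stats::rgamma(n * 5, shape = rep(comp * config$jitterKappa,
                                                   each = n)), n)
      G / rowSums(G)
    } else matrix(rep(comp, each = n), n)
    normal <- !aberrant
    if (config$jitterKappa > 0 && sum(normal) > 1)
      C[normal, ] <- recenterComposition(C[normal, , drop = FALSE], comp)
    l <- if (config$pathSigma > 0)
      stats::rlnorm(n, -config$pathSigma^2 / 2, config$pathSigma)
    else rep(1, n)
    # aberrant overrides
    l[abType == "empty"] <- config$emptyPathlength
    cl <- config$clusterLipid
    clusterComp <- c(cl * 0.6, cl * 0.4, (1 - cl) * 0.5, (1 - cl) * 0.35,
                     (1 - cl) * 0.15)
    C[abType == "cluster", ] <- matrix(rep(clusterComp,
                                           each = sum(abType == "cluster")),
                                       ncol = 5)
    list(C = C, l = l, aberrant = aberrant, abType = abType)
  })
  colnames(st$C) <- .components
  E <- componentMatrix(lib, wn)
  M <- (st$C %*% E) * st$l
  M <- .instrumentMatrix(M, wn, instrument, childSeed(seed, "tile-instr"))
  H <- config$size
  cube <- HyperspectralCube(wn, array(M, c(H, H, length(wn))))
  cube@meta <- list(
    scene = "homogenized",
    truth = list(
      lipid = matrix(100 * (st$C[, 1] + st$C[, 2]), H, H),
      composition = st$C,
      pathlength = matrix(st$l, H, H),
      aberrant = matrix(st$aberrant, H, H),
      aberrantType = matrix(st$abType, H, H),
      analytes = analytesFromComposition(comp)))
  cube
}

#' Intact-scene specification
#'
#' Geometry of a synthetic intact-biomass scene: near-pure lipid droplets
#' (disks), lipid-poor hyphae (random-walk ribbons) and empty background.
#' Droplet radii map to the Mie simulation regime through the pixel pitch.
#'
#' @param height,width scene size in pixels.
#' @param nDroplets,nHyphae structure counts.
#' @param dropletRadiusPx droplet radius range in pixels.
#' @param dropletLipid droplet lipid-fraction range, within `[0.7, 0.95]`.
#' @param hyphaWidthPx hypha ribbon width in pixels.
#' @param hyphaLipid hypha lipid-fraction range (near 0.4).
#' @param pixelPitch micrometres per pixel (default 2.7, FPA scale).
#' @param pathSigma per-pixel log-normal thickness jitter.
#' @param maxOverlap maximum tolerated overlap fraction among painted
#'   structures before the scene counts as overcrowded.
#' @return list of class `"SceneSpec"`.
#' @export
sceneSpec <- function(height = 48, width = 48, nDroplets = 4, nHyphae = 3,
                      dropletRadiusPx = c(2, 6),
                      dropletLipid = c(0.72, 0.92), hyphaWidthPx = 2,
                      hyphaLipid = c(0.35, 0.45), pixelPitch = 2.7,
                      pathSigma = 0.1, maxOverlap = 0.5) {
  if (dropletLipid[1] < 0.7 || dropletLipid[2] > 0.95)
    stop("sceneSpec: droplet lipid fraction range must lie within ",
         "[0.7, 0.95]")
  structure(list(height = height, width = width, nDroplets = nDroplets,
                 nHyphae = nHyphae, dropletRadiusPx = dropletRadiusPx,
                 dropletLipid = dropletLipid, hyphaWidthPx = hyphaWidthPx,
                 hyphaLipid = hyphaLipid, pixelPitch = pixelPitch,
                 pathSigma = pathSigma, maxOverlap = maxOverlap),
            class = "SceneSpec")
}

# Stamp a disk into a label matrix; returns updated matrix and overlap count.
.stampDisk <- function(lab, cy, cx, r, id) {
  H <- nrow(lab); W <- ncol(lab)
  ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  ov <- 0L
  for (y in ys) for (x in xs) {
    if ((y - cy)^2 + (x - cx)^2 <= r^2) {
      if (lab[y, x] != 0L && lab[y, x] != id) ov <- ov + 1L
      lab[y, x] <- id
    }
  }
  list(lab = lab, overlap = ov)
}

#' Render an intact-biomass scene with Mie-distorted pixel spectra
#'
#' Paints lipid droplets and hyphae onto an empty background, assigns each
#' structure a composition and pathlength, generates its clean pixel
#' spectrum (Beer-Lambert + micro lineshape/gain), then Mie-distorts it with
#' [distortSpectrum()] using a sphere radius tied to the local structure
#' (the droplet radius for droplet pixels, half the ribbon width for
#' hyphae). Background pixels carry detector noise only. Per-pixel
#' log-normal thickness jitter multiplies the distorted spectrum, and white
#' noise is added per pixel.
#'
#' @param spec a [sceneSpec()].
#' @param lib a `"BandLibrary"`.
#' @param grid wavenumber grid.
#' @param seed integer seed.
#' @param instrument micro [instrumentConfig()].
#' @param thetaNA,n0,kkScale Mie-distortion parameters shared by all
#'   structures (fill factor and `n0` are drawn per structure within
#'   physical ranges).
#' @return list with `cube` (a [HyperspectralCube-class]) and `maps`, a list
#'   of ground-truth matrices (`total_lipid`, `SFA`, `PFA`, `GlcN` in
#'   percent, and `labels` with values `"background"`, `"droplet"`,
#'   `"hypha"`). The cube's `meta$truth$structures` records each structure's
#'   clean and distorted spectra.
#' @export
renderIntactScene <- function(spec, lib, grid, seed = 1, instrument = NULL,
                              thetaNA = 0.1, n0 = NULL, kkScale = 0.05) {
  stopifnot(inherits(spec, "SceneSpec"))
  if (is.null(instrument)) instrument <- instrumentConfig("micro")
  wn <- if (is(grid, "WavenumberGrid")) grid@values else as.numeric(grid)
  H <- spec$height; W <- spec$width
  sd0 <- childSeed(seed, "scene")
  scene <- withSeed(sd0, {
    lab <- matrix(0L, H, W)
    structures <- list()
    ov <- 0L
    id <- 0L
    if (spec$nHyphae > 0) for (i in seq_len(spec$nHyphae)) {
      id <- id + 1L
      y <- stats::runif(1, 1, H); x <- stats::runif(1, 1, W)
      ang <- stats::runif(1, 0, 2 * pi)
      rw <- spec$hyphaWidthPx / 2
      for (step in seq_len(round(1.5 * max(H, W)))) {
        st <- .stampDisk(lab, y, x, rw, id)
        lab <- st$lab; ov <- ov + st$overlap
        ang <- ang + stats::rnorm(1, 0, 0.15)
        y <- y + sin(ang); x <- x + cos(ang)
        if (y < 1 || y > H || x < 1 || x > W) break
      }
      structures[[id]] <- list(kind = "hypha",
        lipid = stats::runif(1, spec$hyphaLipid[1], spec$hyphaLipid[2]),
        radiusUm = max(0.5, rw * spec$pixelPitch))
    }
    if (spec$nDroplets > 0) for (i in seq_len(spec$nDroplets)) {
      id <- id + 1L
      r <- stats::runif(1, spec$dropletRadiusPx[1], spec$dropletRadiusPx[2])
      cy <- stats::runif(1, 1 + r, H - r); cx <- stats::runif(1, 1 + r, W - r)
      st <- .stampDisk(lab, cy, cx, r, id)
      lab <- st$lab; ov <- ov + st$overlap
      structures[[id]] <- list(kind = "droplet",
        lipid = stats::runif(1, spec$dropletLipid[1], spec$dropletLipid[2]),
        radiusUm = min(18, r * spec$pixelPitch))
    }
    painted <- sum(lab != 0L)
    if (painted > 0 && ov / painted > spec$maxOverlap)
      stop("renderIntactScene: scene overcrowded (overlap fraction ",
           round(ov / painted, 2), " > ", spec$maxOverlap, ")")
    # per-structure composition, pathlength, geometry draws
    for (id in seq_along(structures)) {
      s <- structures[[id]]
      sfaShare <- if (s$kind == "droplet") stats::runif(1, 0.6, 0.8)
                  else stats::runif(1, 0.45, 0.55)
      rest <- 1 - s$lipid
      comp <- c(lipid_sat = s$lipid * sfaShare,
                lipid_unsat = s$lipid * (1 - sfaShare),
                protein = rest * 0.45, carbohydrate = rest * 0.38,
                chitin = rest * 0.17)
      s$comp <- comp
      s$pathlength <- if (s$kind == "droplet") stats::runif(1, 1.0, 1.4)
                      else stats::runif(1, 0.6, 0.9)
      # Fill factors stay within the validity domain of the apparent-
      # absorbance relation (f * Q_ext^NA < 1 for Q up to ~4), matching the
      # augmentation ranges so scene pixels live in the regime the transfer
      # model is trained on.
      s$fillFactor <- stats::runif(1, 0.05, 0.25)
      s$n0 <- if (is.null(n0)) stats::runif(1, 1.35, 1.5) else n0
      structures[[id]] <- s
    }
    list(lab = lab, structures = structures)
  })
  lab <- scene$lab
  structures <- scene$structures
  # clean + distorted spectrum per structure (one Mie evaluation each)
  for (id in seq_along(structures)) {
    s <- structures[[id]]
    clean <- mixtureSpectrum(s$comp, lib, s$pathlength, wn)
    cleanI <- Spectrum(wn, .instrumentMatrix(
      matrix(absorbance(clean), 1), wn,
      instrumentConfig("micro", gainSd = 0, baselineAmp = 0, noiseSd = 0),
      1)[1, ])
    geom <- MieGeometry(s$radiusUm, thetaNA = thetaNA,
                        fillFactor = s$fillFactor, cAbs = 1)
    # The non-particle fraction of a biomass pixel is absorbing matrix of
    # the same structure, so its chemistry passes through the pixel
    # alongside the Mie-scatter contribution of the particle.
    dist <- distortSpectrum(cleanI, geom, n0 = s$n0, kkScale = kkScale,
                            matrixAbsorbance = absorbance(cleanI))
    structures[[id]]$clean <- absorbance(cleanI)
    structures[[id]]$distorted <- absorbance(dist)
  }
  K <- length(wn)
  M <- matrix(0, H * W, K)
  st2 <- withSeed(childSeed(seed, "scene-pixel"), {
    jit <- stats::rlnorm(H * W, -spec$pathSigma^2 / 2, spec$pathSigma)
    noise <- matrix(stats::rnorm(H * W * K, 0, instrument$noiseSd), H * W)
    list(jit = jit, noise = noise)
  })
  idx <- as.vector(lab)
  for (id in seq_along(structures)) {
    rows <- which(idx == id)
    if (length(rows))
      M[rows, ] <- st2$jit[rows] %o% structures[[id]]$distorted
  }
  M <- M + st2$noise
  cube <- HyperspectralCube(wn, array(M, c(H, W, K)))
  kindOf <- vapply(structures, `[[`, "", "kind")
  labels <- matrix("background", H, W)
  labels[lab != 0L] <- kindOf[lab[lab != 0L]]
  analyteMapOf <- function(an) {
    v <- matrix(0, H, W)
    for (id in seq_along(structures)) {
      a <- analytesFromComposition(structures[[id]]$comp)
      v[lab == id] <- a[[an]]
    }
    v
  }
  maps <- list(total_lipid = analyteMapOf("total_lipid"),
               SFA = analyteMapOf("SFA"), PFA = analyteMapOf("PFA"),
               GlcN = analyteMapOf("GlcN"), labels = labels)
  cube@meta <- list(scene = "intact",
                    truth = list(structures = structures, labelIds = lab,
                                 maps = maps))
  list(cube = cube, maps = maps)
}

#' Dataset generation configuration
#'
#' @param grid wavenumber grid for all spectra (default
#'   `syntheticGrid(200)`).
#' @param tile a [tileConfig()] for homogenized tiles.
#' @param scene a [sceneSpec()] for intact scenes (or `NULL` to skip).
#' @param nReplicates technical bulk-measurement replicates per sample.
#' @param lipidRange total-lipid range in percent of biomass; samples are
#'   drawn stratified-uniformly over it (one per equal-width bin, shuffled)
#'   so every generated set spans the full range.
#' @param renderIntact render intact scenes (default TRUE).
#' @return list of class `"DatasetConfig"`.
#' @export
datasetConfig <- function(grid = syntheticGrid(200), tile = tileConfig(),
                          scene = sceneSpec(), nReplicates = 3,
                          lipidRange = c(5, 70), renderIntact = TRUE) {
  structure(list(grid = grid, tile = tile, scene = scene,
                 nReplicates = nReplicates, lipidRange = lipidRange,
                 renderIntact = renderIntact), class = "DatasetConfig")
}

#' Generate a full synthetic dataset
#'
#' For each sample: a bulk composition with total lipid drawn
#' stratified-uniformly over `lipidRange` (mirroring a design that spans a
#' wide analyte range), replicate macroscopic bulk spectra, a homogenized
#' micro tile whose (normal-)pixel-mean composition equals the bulk
#' composition exactly, optionally a Mie-distorted intact scene with
#' ground-truth analyte maps, and reference-analysis rows (total lipid, SFA,
#' PFA, GlcN). Fully reproducible from `(nSamples, config, seed)`.
#'
#' @param nSamples number of samples (>= 4).
#' @param config a [datasetConfig()].
#' @param seed integer seed.
#' @return object of class `"SyntheticDataset"`: list with `samples` (each
#'   has `id`, `composition`, `analytes`, `bulk` (list of
#'   [Spectrum-class]), `homogenized` cube, `intact` list or `NULL`),
#'   `reference` data.frame, `bandLibrary`, `grid`, `config`, `seed`.
#' @export
generateDataset <- function(nSamples = 12, config = datasetConfig(),
                            seed = 1) {
  if (nSamples < 4) stop("generateDataset: need at least 4 samples")
  lib <- generateBandLibrary(seed)
  grid <- config$grid
  lipids <- withSeed(childSeed(seed, "lipids"), {
    edges <- seq(config$lipidRange[1], config$lipidRange[2],
                 length.out = nSamples + 1)
    sample(stats::runif(nSamples, edges[-(nSamples + 1)], edges[-1]))
  })
  samples <- vector("list", nSamples)
  refRows <- list()
  for (i in seq_len(nSamples)) {
    sid <- sprintf("S%02d", i)
    comp <- withSeed(childSeed(seed, "comp", i), {
      L <- lipids[i] / 100
      sfaShare <- stats::runif(1, 0.3, 0.7)
      rest <- as.numeric(stats::rgamma(3, shape = c(4.5, 4.0, 1.5)))
      rest <- rest / sum(rest) * (1 - L)
      c(lipid_sat = L * sfaShare, lipid_unsat = L * (1 - sfaShare),
        protein = rest[1], carbohydrate = rest[2], chitin = rest[3])
    })
    cleanBulk <- mixtureSpectrum(comp, lib, 1, grid)
    bulk <- lapply(seq_len(config$nReplicates), function(r) {
      s <- applyInstrument(cleanBulk, "macro",
                           seed = childSeed(seed, "bulk", i, r))
      s@meta$sample_id <- sid
      s@meta$replicate <- r
      s
    })
    tile <- renderHomogenizedTile(comp, lib, grid, config$tile,
                                  seed = childSeed(seed, "homog", i))
    tile@meta$sample_id <- sid
    intact <- NULL
    if (config$renderIntact && !is.null(config$scene)) {
      intact <- renderIntactScene(config$scene, lib, grid,
                                  seed = childSeed(seed, "intact", i))
      intact$cube@meta$sample_id <- sid
    }
    an <- analytesFromComposition(comp)
    refRows[[i]] <- data.frame(sample_id = sid,
                               analyte = names(an), value = as.numeric(an),
                               replicate = 1L)
    samples[[i]] <- list(id = sid, composition = comp, analytes = an,
                         bulk = bulk, homogenized = tile, intact = intact)
  }
  structure(list(samples = samples,
                 reference = validateReferenceTable(do.call(rbind, refRows)),
                 bandLibrary = lib, grid = grid, config = config,
                 seed = seed),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf(
    "SyntheticDataset: %d samples, %d grid points, seed %s, intact: %s\n",
    length(x$samples), length(x$grid@values), x$seed,
    if (is.null(x$samples[[1]]$intact)) "no" else "yes"))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Cubes as ENVI-style files, bulk spectra and references as CSV,
#' ground-truth maps and the generation config as JSON.
#'
#' @param dataset a `"SyntheticDataset"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  allBulk <- unlist(lapply(dataset$samples, `[[`, "bulk"),
                    recursive = FALSE)
  writeSpectraTable(allBulk, file.path(dir, "bulk_spectra.csv"))
  writeReferenceTable(dataset$reference, file.path(dir, "reference.csv"))
  for (s in dataset$samples) {
    writeCube(s$homogenized, file.path(dir, paste0(s$id, "_homogenized")))
    if (!is.null(s$intact)) {
      writeCube(s$intact$cube, file.path(dir, paste0(s$id, "_intact")))
      jsonlite::write_json(
        lapply(s$intact$maps, function(m) if (is.character(m)) m else m),
        file.path(dir, paste0(s$id, "_truth.json")), digits = NA,
        matrix = "rowmajor")
    }
  }
  jsonlite::write_json(list(seed = dataset$seed,
                            nSamples = length(dataset$samples),
                            gridPoints = length(dataset$grid@values)),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
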