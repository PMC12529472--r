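# Lorenz-Mie forward model for scatter-distorted apparent absorbance of a
# spherical micro-sample under a finite-aperture detector, with a
# Kramers-Kronig-consistent complex refractive index.

#' Mie size parameter
#'
#' `x = 2 pi r nu` with the radius in micrometres and the wavenumber in
#' cm^-1 (1 um = 1e-4 cm), so `x = 2 pi * (r * 1e-4) * nu`.
#'
#' @param radius sphere radius in micrometres (> 0).
#' @param wavenumber wavenumber(s) in cm^-1 (> 0); vectorized.
#' @return dimensionless size parameter(s).
#' @examples
#' sizeParameter(5, 1000 / pi)  # 1
#' @export
sizeParameter <- function(radius, wavenumber) {
  if (any(radius <= 0)) stop("sizeParameter: radius must be positive")
  if (any(wavenumber <= 0)) stop("sizeParameter: wavenumber must be positive")
  2 * pi * (radius * 1e-4) * wavenumber
}

# Wiscombe series-truncation rule.
wiscombeNMax <- function(x) as.integer(ceiling(x + 4.05 * x^(1 / 3) + 2))

.checkMieDomain <- function(x, nMax) {
  if (any(x <= 0)) stop("mie: size parameter must be positive")
  if (any(x > 500)) stop("mie: size parameter beyond stability bound (500)")
  if (any(nMax < 1) || any(nMax > 600))
    stop("mie: series order outside stable range")
}

# Vectorized Mie coefficients: x, m are equal-length vectors (one entry per
# wavenumber); returns nMax x K complex matrices. Logarithmic derivative
# D_n(mx) by downward recursion, Riccati-Bessel psi/chi by upward recursion.
.mieAB <- function(x, m, nMax) {
  .checkMieDomain(x, nMax)
  K <- length(x)
  stopifnot(length(m) == K)
  rho <- m * x
  nStart <- nMax + max(15L, ceiling(1.1 * max(abs(rho))) - nMax + 15L)
  D <- matrix(0i, nMax, K)
  Dn <- rep(0i, K)
  for (n in nStart:1) {
    Dn1 <- n / rho - 1 / (Dn + n / rho)
    if (n <= nMax + 1 && n >= 2) D[n - 1, ] <- Dn1
    if (n == 1) D1 <- Dn1
    Dn <- Dn1
  }
  # psi_{-1} = cos x, psi_0 = sin x; chi_{-1} = -sin x, chi_0 = cos x
  psiM1 <- cos(x); psi0 <- sin(x)
  chiM1 <- -sin(x); chi0 <- cos(x)
  a <- matrix(0i, nMax, K)
  b <- matrix(0i, nMax, K)
  psiPrev <- psi0; psiPrev2 <- psiM1
  chiPrev <- chi0; chiPrev2 <- chiM1
  for (n in seq_len(nMax)) {
    psin <- (2 * n - 1) / x * psiPrev - psiPrev2
    chin <- (2 * n - 1) / x * chiPrev - chiPrev2
    xin <- complex(real = psin, imaginary = -chin)
    xiPrev <- complex(real = psiPrev, imaginary = -chiPrev)
    Dn <- D[n, ]
    fa <- Dn / m + n / x
    fb <- Dn * m + n / x
    a[n, ] <- (fa * psin - psiPrev) / (fa * xin - xiPrev)
    b[n, ] <- (fb * psin - psiPrev) / (fb * xin - xiPrev)
    psiPrev2 <- psiPrev; psiPrev <- psin
    chiPrev2 <- chiPrev; chiPrev <- chin
  }
  list(a = a, b = b)
}

#' Lorenz-Mie expansion coefficients
#'
#' Coefficients `a_n`, `b_n` of the Mie series for a homogeneous sphere,
#' computed with the downward-recursed logarithmic derivative of the
#' Riccati-Bessel function at complex argument and upward Riccati-Bessel
#' recursion at real argument; numerically stable for `x <= 500`.
#'
#' @param x size parameter (scalar, > 0).
#' @param m complex relative refractive index (Im(m) >= 0).
#' @param nMax series truncation order; default is the Wiscombe rule
#'   `ceiling(x + 4.05 x^(1/3) + 2)`.
#' @return list with complex vectors `a` and `b` of length `nMax`.
#' @export
mieCoefficients <- function(x, m, nMax = wiscombeNMax(x)) {
  if (Im(m) < 0) stop("mieCoefficients: Im(m) must be >= 0")
  ab <- .mieAB(x, as.complex(m), as.integer(nMax))
  list(a = ab$a[, 1], b = ab$b[, 1])
}

# Series efficiencies from coefficient matrices (nMax x K).
.mieQSeries <- function(ab, x) {
  n <- seq_len(nrow(ab$a))
  w <- 2 * n + 1
  qSca <- 2 / x^2 * colSums(w * (Mod(ab$a)^2 + Mod(ab$b)^2))
  qExt <- 2 / x^2 * colSums(w * Re(ab$a + ab$b))
  list(qSca = qSca, qExt = qExt, qAbs = qExt - qSca)
}

#' Total Mie efficiencies from the series
#'
#' `Q_sca = (2/x^2) sum (2n+1)(|a_n|^2 + |b_n|^2)`,
#' `Q_ext = (2/x^2) sum (2n+1) Re(a_n + b_n)`, `Q_abs = Q_ext - Q_sca`.
#'
#' @inheritParams mieCoefficients
#' @return list with `qSca`, `qExt`, `qAbs`.
#' @export
mieEfficiencies <- function(x, m, nMax = wiscombeNMax(x)) {
  ab <- .mieAB(x, as.complex(m), as.integer(nMax))
  q <- .mieQSeries(ab, x)
  lapply(q, as.numeric)
}

# Angular functions pi_n(mu), tau_n(mu) for all n <= nMax at all mu:
# returns list of nMax x nTheta matrices.
.angularFunctions <- function(nMax, mu) {
  nT <- length(mu)
  Pi <- matrix(0, nMax, nT)
  Tau <- matrix(0, nMax, nT)
  piPrev2 <- rep(0, nT)   # pi_0
  piPrev <- rep(1, nT)    # pi_1
  for (n in seq_len(nMax)) {
    Pi[n, ] <- piPrev
    Tau[n, ] <- n * mu * piPrev - (n + 1) * piPrev2
    piNext <- ((2 * n + 1) * mu * piPrev - (n + 1) * piPrev2) / n
    piPrev2 <- piPrev
    piPrev <- piNext
  }
  list(Pi = Pi, Tau = Tau)
}

#' Scattering amplitudes S1, S2
#'
#' Diagonal elements of the amplitude scattering matrix at the given
#' scattering angles, from the Mie series with the angular functions
#' `pi_n`, `tau_n` computed by stable upward recurrences.
#'
#' @inheritParams mieCoefficients
#' @param thetas scattering angles in radians, within `[0, pi]`.
#' @return list with `theta` and complex vectors `S1`, `S2`.
#' @export
scatteringAmplitudes <- function(x, m, thetas, nMax = wiscombeNMax(x)) {
  if (any(thetas < 0 | thetas > pi))
    stop("scatteringAmplitudes: angles must lie in [0, pi]")
  ab <- mieCoefficients(x, m, nMax)
  ang <- .angularFunctions(nMax, cos(thetas))
  n <- seq_len(nMax)
  cn <- (2 * n + 1) / (n * (n + 1))
  S1 <- as.vector(t(ang$Pi) %*% (cn * ab$a) + t(ang$Tau) %*% (cn * ab$b))
  S2 <- as.vector(t(ang$Tau) %*% (cn * ab$a) + t(ang$Pi) %*% (cn * ab$b))
  list(theta = thetas, S1 = S1, S2 = S2)
}

# Vectorized aperture-restricted scattering efficiency:
# Q_sca^NA = (1/x^2) int_{thetaNA}^{pi} (|S1|^2 + |S2|^2) sin(theta) dtheta,
# Gauss-Legendre quadrature with node doubling until relative change < tol.
.qScaNAVec <- function(x, m, thetaNA, tol = 1e-6, nodes0 = 64L,
                       nodeCap = 4096L) {
  if (thetaNA >= pi) return(rep(0, length(x)))
  nMax <- wiscombeNMax(max(x))
  ab <- .mieAB(x, m, nMax)
  n <- seq_len(nMax)
  cn <- (2 * n + 1) / (n * (n + 1))
  A <- cn * ab$a   # nMax x K
  B <- cn * ab$b
  evalQuad <- function(nn) {
    gl <- pracma::gaussLegendre(nn, thetaNA, pi)
    ang <- .angularFunctions(nMax, cos(gl$x))
    S1 <- t(ang$Pi) %*% A + t(ang$Tau) %*% B   # nn x K
    S2 <- t(ang$Tau) %*% A + t(ang$Pi) %*% B
    integrand <- (Mod(S1)^2 + Mod(S2)^2) * sin(gl$x)
    as.numeric(t(integrand) %*% gl$w) / x^2
  }
  nn <- nodes0
  prev <- evalQuad(nn)
  repeat {
    nn <- 2L * nn
    cur <- evalQuad(nn)
    relchg <- max(abs(cur - prev) / pmax(abs(cur), 1e-300))
    if (relchg < tol) return(cur)
    if (nn >= nodeCap) {
      warning("qScaNA: quadrature not converged at node cap (",
              nodeCap, " nodes); returning best estimate")
      return(cur)
    }
    prev <- cur
  }
}

#' Aperture-restricted scattering efficiency
#'
#' The scattering efficiency restricted to angles outside the detector's
#' effective numerical aperture:
#' `Q_sca^NA = (1/x^2) * integral_{thetaNA}^{pi} (|S1|^2+|S2|^2) sin(theta)
#' dtheta`, evaluated by Gauss-Legendre quadrature with node doubling until
#' the relative change is below `tol`. At `thetaNA = 0` it equals the series
#' `Q_sca`; it is non-increasing in `thetaNA`.
#'
#' @inheritParams mieCoefficients
#' @param thetaNA aperture half-angle in radians, `0 <= thetaNA <= pi`.
#' @param tol relative convergence tolerance for node doubling.
#' @return numeric scalar.
#' @export
qScaNA <- function(x, m, thetaNA, tol = 1e-6) {
  if (thetaNA < 0 || thetaNA > pi)
    stop("qScaNA: thetaNA must lie in [0, pi]")
  .qScaNAVec(x, as.complex(m), thetaNA, tol)[1]
}

#' Complex refractive index model
#'
#' `n(nu) = n0 + n_r(nu) + i n_i(nu)` on a wavenumber grid. The imaginary
#' part is proportional to a scatter-free absorbance spectrum
#' (`n_i = kkScale * A`), and the fluctuating real part is its
#' Kramers-Kronig partner, computed by [kramersKronig()].
#'
#' @param grid a [WavenumberGrid-class] or numeric wavenumbers.
#' @param n0 constant real baseline index, in `[1, 2.5]`.
#' @param nI imaginary part per wavenumber (>= 0), or `NULL` to derive it
#'   from `absorbance` via `kkScale`.
#' @param absorbance optional scatter-free absorbance spectrum used when
#'   `nI` is `NULL`.
#' @param kkScale proportionality constant linking absorbance to `n_i`
#'   (default 0.05: a unit-max absorbance spectrum peaks at `n_i = 0.05`,
#'   typical of biological soft matter).
#' @return list of class `"RefractiveIndexModel"` with elements `grid`,
#'   `n0`, `nR`, `nI`, `kkScale`.
#' @export
refractiveIndexModel <- function(grid, n0, nI = NULL, absorbance = NULL,
                                 kkScale = 0.05) {
  if (!is(grid, "WavenumberGrid")) grid <- WavenumberGrid(grid)
  if (is.null(nI)) {
    if (is.null(absorbance))
      stop("refractiveIndexModel: supply nI or absorbance")
    nI <- kkScale * absorbance
  }
  if (any(nI < 0)) stop("refractiveIndexModel: n_i must be >= 0")
  if (n0 < 1 || n0 > 2.5)
    stop("refractiveIndexModel: n0 must lie in [1, 2.5]")
  if (length(nI) != length(grid@values))
    stop("refractiveIndexModel: n_i length must equal grid length")
  nR <- kramersKronig(nI, grid)
  structure(list(grid = grid, n0 = n0, nR = nR, nI = nI,
                 kkScale = kkScale),
            class = "RefractiveIndexModel")
}

#' Kramers-Kronig partner of the imaginary refractive index
#'
#' Computes the fluctuating real part `n_r` from the imaginary part `n_i`
#' as the Hilbert-transform partner on a zero-padded, evenly resampled
#' wavenumber axis (FFT implementation), mean-centered over the grid. For a
#' Lorentzian `n_i(nu) = h g^2 / ((nu - nu0)^2 + g^2)` the result is the
#' analytic dispersive Lorentzian `h g (nu0 - nu) / ((nu - nu0)^2 + g^2)`;
#' edge artifacts are confined to roughly the outer 10% of the grid on each
#' side (the guard band).
#'
#' @param nI imaginary part per wavenumber, >= 0, with its support
#'   effectively inside the grid.
#' @param grid a [WavenumberGrid-class] or numeric wavenumbers (>= 16
#'   points for the padding scheme).
#' @return numeric vector `n_r` on the grid, zero-mean.
#' @export
kramersKronig <- function(nI, grid) {
  v <- if (is(grid, "WavenumberGrid")) grid@values else as.numeric(grid)
  N <- length(v)
  if (N < 16) stop("kramersKronig: grid too short for padding scheme")
  if (length(nI) != N) stop("kramersKronig: length mismatch")
  dv <- diff(v)
  even <- (max(dv) - min(dv)) < 1e-8 * mean(dv)
  if (!even) {
    ve <- seq(v[1], v[N], length.out = N)
    u <- stats::approx(v, nI, xout = ve)$y
  } else {
    ve <- v
    u <- nI
  }
  P <- 2^ceiling(log2(4 * N))
  buf <- numeric(P)
  off <- floor((P - N) / 2)
  buf[off + seq_len(N)] <- u
  # analytic signal via FFT; Im part = Hilbert transform with the
  # (s - t) kernel convention
  H <- numeric(P)
  H[1] <- 1
  if (P %% 2 == 0) {
    H[P / 2 + 1] <- 1
    H[2:(P / 2)] <- 2
  } else {
    H[2:((P + 1) / 2)] <- 2
  }
  z <- stats::fft(stats::fft(buf) * H, inverse = TRUE) / P
  h <- Im(z)[off + seq_len(N)]
  nR <- -h
  if (!even) nR <- stats::approx(ve, nR, xout = v)$y
  nR - mean(nR)
}

#' Efficiency curves for a sphere across a wavenumber grid
#'
#' Per-wavenumber Mie efficiencies for a [MieGeometry-class] and a
#' refractive-index model: the series totals `q_ext_total`, `q_sca_total`,
#' `q_abs = q_ext_total - q_sca_total`, the aperture-restricted `q_sca_na`,
#' and the combination `q_ext_na = cAbs * q_abs + q_sca_na`.
#'
#' @param nModel a `"RefractiveIndexModel"` from [refractiveIndexModel()].
#' @param geometry a [MieGeometry-class]; must share the model's grid
#'   implicitly via the radius/wavenumber product.
#' @param tol quadrature tolerance passed to the angular integration.
#' @return data.frame with columns `wavenumber`, `q_ext_na`, `q_sca_na`,
#'   `q_abs`, `q_sca_total`, `q_ext_total`.
#' @export
efficiencyCurves <- function(nModel, geometry, tol = 1e-6) {
  stopifnot(inherits(nModel, "RefractiveIndexModel"),
            is(geometry, "MieGeometry"))
  wn <- nModel$grid@values
  x <- sizeParameter(geometry@radius, wn)
  m <- complex(real = nModel$n0 + nModel$nR, imaginary = nModel$nI)
  nMax <- wiscombeNMax(max(x))
  ab <- .mieAB(x, m, nMax)
  q <- .mieQSeries(ab, x)
  qNA <- .qScaNAVec(x, m, geometry@thetaNA, tol)
  data.frame(
    wavenumber = wn,
    q_ext_na = geometry@cAbs * q$qAbs + qNA,
    q_sca_na = qNA,
    q_abs = q$qAbs,
    q_sca_total = q$qSca,
    q_ext_total = q$qExt)
}

#' Export efficiency curves as CSV
#'
#' @param curves data.frame from [efficiencyCurves()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportEfficiencyCurves <- function(curves, path) {
  utils::write.csv(curves[, c("wavenumber", "q_ext_na", "q_sca_na",
                              "q_abs")], path, row.names = FALSE)
  invisible(path)
}

#' Apparent absorbance under non-exponential attenuation
#'
#' `A = -log10(1 - f * Q_ext^NA)`, the scatter-distorted apparent absorbance
#' of a micro-sample that removes a fraction `f * Q_ext^NA` of the radiation
#' reaching the detector aperture (`f = G / g_NA`, the sample-to-aperture
#' cross-section ratio). Arguments of the logarithm are clipped to
#' `>= 1e-6` (flagged via the `"saturated"` attribute) unless
#' `onSaturate = "error"`.
#'
#' @param qExtNA extinction efficiency per wavenumber.
#' @param fillFactor `f` in (0, 1].
#' @param onSaturate `"clip"` (default) or `"error"`.
#' @return numeric absorbance; attribute `saturated` is `TRUE` if clipping
#'   occurred.
#' @examples
#' apparentAbsorbance(0.5, 1)  # -log10(0.5) = 0.30103
#' @export
apparentAbsorbance <- function(qExtNA, fillFactor, onSaturate = c("clip",
                                                                  "error")) {
  onSaturate <- match.arg(onSaturate)
  if (fillFactor <= 0 || fillFactor > 1)
    stop("apparentAbsorbance: fillFactor must lie in (0, 1]")
  arg <- 1 - fillFactor * qExtNA
  sat <- any(arg < 1e-6)
  if (sat && onSaturate == "error")
    stop("apparentAbsorbance: saturation (1 - f * Q <= 0)")
  A <- -log10(pmax(arg, 1e-6))
  attr(A, "saturated") <- sat
  A
}

#' Mie-distort a clean spectrum
#'
#' The forward simulation used for physics-based augmentation: builds the
#' complex refractive index `n = n0 + n_r + i n_i` with
#' `n_i = kkScale * A_clean` and `n_r` its Kramers-Kronig partner, evaluates
#' the efficiency curves for the geometry, and returns the apparent
#' absorbance `-log10(1 - f * Q_ext^NA)`. Deterministic for fixed inputs.
#'
#' @param clean a [Spectrum-class] with non-negative absorbance.
#' @param geometry a [MieGeometry-class].
#' @param n0 constant real baseline index (default 1.4).
#' @param kkScale absorbance-to-`n_i` proportionality (default 0.05).
#' @param tol quadrature tolerance.
#' @param onSaturate passed to [apparentAbsorbance()].
#' @param matrixAbsorbance optional absorbance spectrum of the non-particle
#'   fraction of the measurement area. The apparent-absorbance relation
#'   `A = -log10(1 - f Q)` is the two-component pixel transmission
#'   `T = (1-f) T_bg + f (1 - Q)` with an empty background (`T_bg = 1`);
#'   inside a biomass structure the background is absorbing matrix, so
#'   `T_bg = 10^(-A_matrix)`. `NULL` (default) keeps the empty-background
#'   relation exactly.
#' @return a [Spectrum-class] on the same grid (meta gains
#'   `distorted = TRUE`).
#' @export
distortSpectrum <- function(clean, geometry, n0 = 1.4, kkScale = 0.05,
                            tol = 1e-6, onSaturate = "clip",
                            matrixAbsorbance = NULL) {
  a <- absorbance(clean)
  if (any(a < -1e-9))
    stop("distortSpectrum: clean absorbance must be >= 0")
  a <- pmax(a, 0)
  nm <- refractiveIndexModel(clean@grid, n0 = n0, nI = kkScale * a,
                             kkScale = kkScale)
  cv <- efficiencyCurves(nm, geometry, tol = tol)
  if (is.null(matrixAbsorbance)) {
    A <- apparentAbsorbance(cv$q_ext_na, geometry@fillFactor,
                            onSaturate = onSaturate)
  } else {
    if (length(matrixAbsorbance) != length(a))
      stop("distortSpectrum: matrixAbsorbance length must match the grid")
    f <- geometry@fillFactor
    Tpix <- (1 - f) * 10^(-pmax(matrixAbsorbance, 0)) +
      f * pmax(1 - cv$q_ext_na, 0)
    sat <- any(Tpix < 1e-6)
    if (sat && identical(onSaturate, "error"))
      stop("distortSpectrum: saturation (pixel transmission <= 0)")
    A <- -log10(pmax(Tpix, 1e-6))
    attr(A, "saturated") <- sat
  }
  mt <- clean@meta
  mt$distorted <- TRUE
  out <- new("Spectrum", grid = clean@grid, absorbance = as.numeric(A),
             meta = mt)
  attr(out, "saturated") <- attr(A, "saturated")
  out
}
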