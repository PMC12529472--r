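#' @import methods
NULL

#' Wavenumber grid
#'
#' The spectral axis shared by spectra and hyperspectral cubes: strictly
#' monotonic wavenumbers in reciprocal centimetres. Grids read from files in
#' descending order are canonicalized to ascending order on construction; all
#' internal numerics assume ascending grids.
#'
#' @slot values numeric, wavenumbers in cm^-1, strictly increasing, all > 0.
#' @slot spacing numeric(1), nominal digital spacing in cm^-1 (median of the
#'   first differences).
#' @export
setClass("WavenumberGrid",
  representation(values = "numeric", spacing = "numeric"))

setValidity("WavenumberGrid", function(object) {
  v <- object@values
  if (length(v) < 8L)
    return("grid must have at least 8 points")
  if (anyNA(v) || any(!is.finite(v)))
    return("grid values must be finite")
  if (any(v <= 0))
    return("wavenumbers must be positive")
  if (any(diff(v) <= 0))
    return("grid must be strictly increasing after canonicalization")
  TRUE
})

#' Construct a wavenumber grid
#'
#' @param values wavenumbers in cm^-1; strictly monotonic (either direction;
#'   descending input is reversed to the internal ascending convention).
#' @return A [WavenumberGrid-class] object.
#' @examples
#' g <- WavenumberGrid(seq(900, 3845, by = 3.8522))
#' length(wavenumbers(g))
#' @export
WavenumberGrid <- function(values) {
  values <- as.numeric(values)
  if (length(values) >= 2 && all(diff(values) < 0))
    values <- rev(values)
  sp <- if (length(values) >= 2) stats::median(diff(values)) else NA_real_
  new("WavenumberGrid", values = values, spacing = sp)
}

#' A single absorbance spectrum
#'
#' Absorbance (in AU) against a [WavenumberGrid-class]. The `meta` list
#' carries sample id, replicate id and an instrument tag (`"macro"` for bulk
#' HTS-FTIR, `"micro"` for imaging pixel spectra).
#'
#' @slot grid a [WavenumberGrid-class].
#' @slot absorbance numeric, one finite value per grid point.
#' @slot meta list of free-form metadata (`sample_id`, `replicate`,
#'   `instrument`, ...).
#' @export
setClass("Spectrum",
  representation(grid = "WavenumberGrid", absorbance = "numeric",
                 meta = "list"))

setValidity("Spectrum", function(object) {
  if (length(object@absorbance) != length(object@grid@values))
    return("absorbance length must equal grid length")
  if (anyNA(object@absorbance) || any(!is.finite(object@absorbance)))
    return("absorbance values must be finite")
  TRUE
})

#' Construct a spectrum
#'
#' @param grid a [WavenumberGrid-class] or a numeric vector of wavenumbers.
#' @param absorbance numeric absorbance values, one per grid point, in the
#'   order of `grid` as supplied (reordered together with a descending grid).
#' @param ... metadata entries stored in `meta` (e.g. `sample_id`,
#'   `replicate`, `instrument`).
#' @return A [Spectrum-class] object.
#' @examples
#' s <- Spectrum(seq(1000, 1800, by = 4), rep(0.1, 201), sample_id = "s1")
#' @export
Spectrum <- function(grid, absorbance, ...) {
  if (!is(grid, "WavenumberGrid")) {
    raw <- as.numeric(grid)
    if (length(raw) >= 2 && all(diff(raw) < 0))
      absorbance <- rev(absorbance)
    grid <- WavenumberGrid(raw)
  }
  new("Spectrum", grid = grid, absorbance = as.numeric(absorbance),
      meta = list(...))
}

#' Hyperspectral absorbance cube
#'
#' An H x W image of pixel spectra sharing one wavenumber grid, with a
#' logical validity mask (`TRUE` = retained pixel). The spectral axis is the
#' third array dimension.
#'
#' @slot grid a [WavenumberGrid-class]; its length equals `dim(data)[3]`.
#' @slot data numeric H x W x K array of absorbance.
#' @slot mask logical H x W matrix.
#' @slot meta list (`sample_id`, `scene` in `c("homogenized", "intact")`,
#'   ground-truth annotations for synthetic scenes, ...).
#' @export
setClass("HyperspectralCube",
  representation(grid = "WavenumberGrid", data = "array", mask = "matrix",
                 meta = "list"))

setValidity("HyperspectralCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-d array (H x W x K)")
  if (d[3] != length(object@grid@values))
    return("spectral dimension must equal grid length")
  if (!is.logical(object@mask))
    return("mask must be logical")
  if (!all(dim(object@mask) == d[1:2]))
    return("mask shape must match image dimensions")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    return("cube data must be finite")
  TRUE
})

#' Construct a hyperspectral cube
#'
#' @param grid a [WavenumberGrid-class] or numeric wavenumbers (length K).
#' @param data numeric H x W x K array (a descending grid reverses the
#'   spectral axis together with the grid).
#' @param mask logical H x W matrix; default all `TRUE`.
#' @param ... metadata entries.
#' @return A [HyperspectralCube-class] object.
#' @export
HyperspectralCube <- function(grid, data, mask = NULL, ...) {
  if (!is(grid, "WavenumberGrid")) {
    raw <- as.numeric(grid)
    if (length(raw) >= 2 && all(diff(raw) < 0)) {
      data <- data[, , rev(seq_len(dim(data)[3])), drop = FALSE]
      raw <- rev(raw)
    }
    grid <- WavenumberGrid(raw)
  }
  if (is.null(mask))
    mask <- matrix(TRUE, dim(data)[1], dim(data)[2])
  new("HyperspectralCube", grid = grid, data = data, mask = mask,
      meta = list(...))
}

#' Sphere and detector geometry for the Mie forward model
#'
#' Geometry of a spherical micro-sample observed through a finite effective
#' numerical aperture. `fillFactor` is the ratio G/g_NA of the sample's
#' geometric cross-section to the detector's effective-aperture
#' cross-section; `cAbs` weights the absorption efficiency in the
#' extinction-efficiency combination Q_ext^NA = c Q_abs + Q_sca^NA.
#'
#' @slot radius numeric(1), sphere radius in micrometres, > 0.
#' @slot thetaNA numeric(1), effective numerical-aperture half-angle in
#'   radians, in `[0, pi/2)`.
#' @slot fillFactor numeric(1) in (0, 1].
#' @slot cAbs numeric(1) > 0.
#' @export
setClass("MieGeometry",
  representation(radius = "numeric", thetaNA = "numeric",
                 fillFactor = "numeric", cAbs = "numeric"))

setValidity("MieGeometry", function(object) {
  if (length(object@radius) != 1 || object@radius <= 0)
    return("radius must be a single positive value (micrometres)")
  if (object@thetaNA < 0 || object@thetaNA >= pi / 2)
    return("thetaNA must lie in [0, pi/2)")
  if (object@fillFactor <= 0 || object@fillFactor > 1)
    return("fillFactor must lie in (0, 1]")
  if (object@cAbs <= 0)
    return("cAbs must be positive")
  TRUE
})

#' Construct a Mie geometry
#'
#' @param radius sphere radius in micrometres.
#' @param thetaNA effective aperture half-angle in radians (default 0.1,
#'   small compared with the arcsin(0.4) = 0.41 rad of a 0.4-NA objective,
#'   reflecting the pixel-limited effective aperture of an FPA detector).
#' @param fillFactor sample/aperture cross-section ratio in (0, 1].
#' @param cAbs weight of `Q_abs` in the extinction combination.
#' @return A [MieGeometry-class] object.
#' @export
MieGeometry <- function(radius, thetaNA = 0.1, fillFactor = 0.5, cAbs = 1) {
  new("MieGeometry", radius = as.numeric(radius),
      thetaNA = as.numeric(thetaNA), fillFactor = as.numeric(fillFactor),
      cAbs = as.numeric(cAbs))
}

#' A trained (or initialized) network
#'
#' Container for the learned transfer and calibration networks: architecture
#' spec, parameters, frozen normalization statistics, training log and
#' provenance (seed, config, data fingerprint). Models are created untrained
#' by [buildModel()] and fitted by [trainModel()].
#'
#' @slot spec list, the architecture description from [networkSpec()].
#' @slot params list of numeric arrays (layer weights and biases).
#' @slot norm list of normalization statistics, fitted on training data only.
#' @slot log list, loss per epoch and early-stopping bookkeeping.
#' @slot provenance list (seed, train config, data hash, package version).
#' @export
setClass("TrainedModel",
  representation(spec = "list", params = "list", norm = "list",
                 log = "list", provenance = "list"))

setValidity("TrainedModel", function(object) {
  if (!is.character(object@spec$task))
    return("spec$task missing")
  if (!object@spec$task %in% c("transfer", "calibration"))
    return("spec$task must be 'transfer' or 'calibration'")
  TRUE
})
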