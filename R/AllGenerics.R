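#' Wavenumber axis of an object
#'
#' @param x a [WavenumberGrid-class], [Spectrum-class] or
#'   [HyperspectralCube-class].
#' @return numeric vector of wavenumbers in cm^-1 (ascending).
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "WavenumberGrid", function(x) x@values)

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "Spectrum", function(x) x@grid@values)

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "HyperspectralCube", function(x) x@grid@values)

#' Absorbance values of a spectrum
#'
#' @param x a [Spectrum-class].
#' @return numeric vector of absorbance (AU).
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname absorbance
#' @export
setMethod("absorbance", "Spectrum", function(x) x@absorbance)

#' Pixel data of a hyperspectral cube
#'
#' @param x a [HyperspectralCube-class].
#' @return H x W x K numeric array.
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))

#' @rdname cubeData
#' @export
setMethod("cubeData", "HyperspectralCube", function(x) x@data)

#' Validity mask of a hyperspectral cube
#'
#' @param x a [HyperspectralCube-class].
#' @return logical H x W matrix (`TRUE` = valid/retained pixel).
#' @export
setGeneric("cubeMask", function(x) standardGeneric("cubeMask"))

#' @rdname cubeMask
#' @export
setMethod("cubeMask", "HyperspectralCube", function(x) x@mask)

#' Metadata list of an object
#'
#' @param x a [Spectrum-class] or [HyperspectralCube-class].
#' @return named list of metadata.
#' @export
setGeneric("meta", function(x) standardGeneric("meta"))

#' @rdname meta
#' @export
setMethod("meta", "Spectrum", function(x) x@meta)

#' @rdname meta
#' @export
setMethod("meta", "HyperspectralCube", function(x) x@meta)

#' Resample a spectrum onto a target wavenumber grid
#'
#' Linear interpolation onto `target`; the target range must lie within the
#' source range (no extrapolation). Macroscopic bulk spectra are resampled
#' this way onto the microscopic pixel grid before pairing.
#'
#' @param x a [Spectrum-class].
#' @param target a [WavenumberGrid-class] (or numeric wavenumbers).
#' @return a [Spectrum-class] on `target`.
#' @export
setGeneric("resampleToGrid", function(x, target)
  standardGeneric("resampleToGrid"))

#' Trim an object to a wavenumber window
#'
#' Keeps grid points with `lo <= wavenumber <= hi` (order preserved); used to
#' harmonize the macroscopic 4000-400 cm^-1 range with the microscopic
#' 3845-900 cm^-1 range.
#'
#' @param x a [Spectrum-class] or [HyperspectralCube-class].
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @return object of the same class on the trimmed grid.
#' @export
setGeneric("trimRange", function(x, lo, hi) standardGeneric("trimRange"))

setMethod("show", "WavenumberGrid", function(object) {
  v <- object@values
  cat(sprintf("WavenumberGrid: %d points, %.4f-%.4f cm^-1, spacing %.4f\n",
              length(v), min(v), max(v), object@spacing))
})

setMethod("show", "Spectrum", function(object) {
  v <- object@grid@values
  id <- object@meta$sample_id
  cat(sprintf("Spectrum%s: %d points, %.1f-%.1f cm^-1, A in [%.4g, %.4g]\n",
              if (is.null(id)) "" else paste0(" [", id, "]"),
              length(v), min(v), max(v),
              min(object@absorbance), max(object@absorbance)))
})

setMethod("show", "HyperspectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "HyperspectralCube: %d x %d pixels, %d wavenumbers (%.1f-%.1f cm^-1)\n",
    d[1], d[2], d[3], min(object@grid@values), max(object@grid@values)))
  cat(sprintf("  valid pixels: %d / %d; scene: %s\n", sum(object@mask),
              length(object@mask),
              if (is.null(object@meta$scene)) "?" else object@meta$scene))
})

setMethod("show", "MieGeometry", function(object) {
  cat(sprintf(
    "MieGeometry: r = %.3g um, thetaNA = %.3g rad, f = %.3g, cAbs = %.3g\n",
    object@radius, object@thetaNA, object@fillFactor, object@cAbs))
})

setMethod("show", "TrainedModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf("TrainedModel (%s): %d parameters, input length %d, %s\n",
              object@spec$task, np, object@spec$inputLength,
              if (isTRUE(object@log$trained)) sprintf(
                "trained (%d epochs, best val loss %.4g)",
                length(object@log$trainLoss), object@log$bestValLoss)
              else "untrained"))
})
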