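# Spectral data model, resampling and file I/O shared by all stages.

#' Default microscopic wavenumber grid
#'
#' The FPA imaging grid: 900-3845 cm^-1 at a digital spacing of 3.8522 cm^-1
#' (765 points).
#'
#' @return a [WavenumberGrid-class].
#' @export
defaultMicroGrid <- function() {
  WavenumberGrid(seq(900, 3845, by = 3.8522))
}

#' Reduced synthetic grid
#'
#' An evenly spaced grid over the same span as [defaultMicroGrid()] with a
#' configurable number of points; coarse grids keep simulation and training
#' runs fast while covering the ester (1745 cm^-1) and amide I
#' (1600-1700 cm^-1) bands.
#'
#' @param nPoints number of grid points (default 200).
#' @param lo,hi span in cm^-1.
#' @return a [WavenumberGrid-class].
#' @export
syntheticGrid <- function(nPoints = 200, lo = 900, hi = 3845) {
  WavenumberGrid(seq(lo, hi, length.out = nPoints))
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards. All package randomness funnels through this.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Derive a child seed from (seed, tag) deterministically, staying < 2^31.
childSeed <- function(seed, ...) {
  tags <- paste(c(seed, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h) + 1L
}

#' @rdname resampleToGrid
#' @export
setMethod("resampleToGrid", "Spectrum", function(x, target) {
  if (!is(target, "WavenumberGrid"))
    target <- WavenumberGrid(target)
  src <- x@grid@values
  tgt <- target@values
  eps <- 1e-9 * max(abs(src))
  if (min(tgt) < min(src) - eps || max(tgt) > max(src) + eps)
    stop("resampleToGrid: target range exceeds source range ",
         "(extrapolation not allowed)")
  a <- stats::approx(src, x@absorbance, xout = tgt, rule = 1)$y
  # endpoints may fall epsilon outside due to float noise; clamp
  if (anyNA(a)) {
    a[is.na(a) & tgt <= src[1]] <- x@absorbance[1]
    a[is.na(a) & tgt >= src[length(src)]] <- x@absorbance[length(src)]
  }
  new("Spectrum", grid = target, absorbance = a, meta = x@meta)
})

#' @rdname trimRange
#' @export
setMethod("trimRange", "Spectrum", function(x, lo, hi) {
  keep <- trimIndex(x@grid@values, lo, hi)
  new("Spectrum", grid = WavenumberGrid(x@grid@values[keep]),
      absorbance = x@absorbance[keep], meta = x@meta)
})

#' @rdname trimRange
#' @export
setMethod("trimRange", "HyperspectralCube", function(x, lo, hi) {
  keep <- trimIndex(x@grid@values, lo, hi)
  new("HyperspectralCube", grid = WavenumberGrid(x@grid@values[keep]),
      data = x@data[, , keep, drop = FALSE], mask = x@mask, meta = x@meta)
})

trimIndex <- function(v, lo, hi) {
  if (lo >= hi) stop("trimRange: lo must be < hi")
  keep <- which(v >= lo & v <= hi)
  if (length(keep) == 0)
    stop("trimRange: window [", lo, ", ", hi, "] contains no grid points")
  keep
}

## ---- hyperspectral cube I/O -------------------------------------------

#' Write a hyperspectral cube to disk
#'
#' Two dialects are supported: `"envi"` writes a plain-text `.hdr` header
#' plus an IEEE little-endian float64 binary in band-sequential (BSQ)
#' interleave, with the validity mask in a sidecar `<path>.mask` text file;
#' `"json"` writes a single self-describing JSON file. Both round-trip the
#' grid, data and mask bit-exactly at float64 width.
#'
#' @param cube a [HyperspectralCube-class].
#' @param path output path. For `"envi"`, `path` is the binary file and
#'   `<path>.hdr` / `<path>.mask` are written next to it.
#' @param format `"envi"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @seealso [readCube()]
#' @export
writeCube <- function(cube, path, format = c("envi", "json")) {
  format <- match.arg(format)
  d <- dim(cube@data)
  if (format == "json") {
    obj <- list(
      format = "micral-cube", version = 1L,
      wavenumbers = cube@grid@values,
      dims = d,
      data = as.numeric(cube@data),
      mask = as.integer(cube@mask),
      meta = metaForJSON(cube@meta))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  # ENVI-style: BSQ, data type 5 (float64), little endian
  hdr <- c(
    "ENVI",
    "description = {micral hyperspectral cube}",
    paste0("samples = ", d[2]),
    paste0("lines = ", d[1]),
    paste0("bands = ", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Wavenumber",
    paste0("wavelength = {",
           paste(formatC(cube@grid@values, digits = 17, format = "g"),
                 collapse = ", "), "}"),
    paste0("; meta = ",
           jsonlite::toJSON(metaForJSON(cube@meta), auto_unbox = TRUE,
                            digits = NA)))
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: band-major, then lines (rows), then samples (cols)
  bsq <- aperm(cube@data, c(2, 1, 3))  # sample fastest, then line, then band
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(bsq), con, size = 8, endian = "little")
  writeLines(apply(cube@mask, 1, function(r)
    paste(as.integer(r), collapse = " ")), paste0(path, ".mask"))
  invisible(path)
}

metaForJSON <- function(m) {
  m[vapply(m, function(x)
    is.atomic(x) || is.list(x), logical(1))]
}

#' Read a hyperspectral cube from disk
#'
#' Auto-detects the dialect written by [writeCube()]: a JSON file or an
#' ENVI-style header + binary pair. Descending wavenumber grids are
#' canonicalized to ascending order, reversing the spectral axis with them.
#'
#' @param path path given to [writeCube()].
#' @return a [HyperspectralCube-class].
#' @export
readCube <- function(path) {
  if (!file.exists(path) && !file.exists(paste0(path, ".hdr")))
    stop("readCube: no such file: ", path)
  firstByte <- tryCatch(readBin(path, "raw", 1), error = function(e) raw(0))
  if (length(firstByte) && rawToChar(firstByte) %in% c("{", "["))
    return(readCubeJSON(path))
  readCubeENVI(path)
}

readCubeJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "micral-cube")
    stop("readCube: not a micral cube JSON file")
  d <- as.integer(obj$dims)
  if (length(obj$data) != prod(d))
    stop("readCube: data length does not match dims")
  if (length(obj$wavenumbers) != d[3])
    stop("readCube: wavenumber length does not match spectral dimension")
  mask <- matrix(as.logical(obj$mask), d[1], d[2])
  mt <- if (is.null(obj$meta)) list() else as.list(obj$meta)
  HyperspectralCube(obj$wavenumbers, array(obj$data, d), mask) |>
    setCubeMeta(mt)
}

readCubeENVI <- function(path) {
  hdrPath <- paste0(path, ".hdr")
  if (!file.exists(hdrPath)) stop("readCube: missing ENVI header ", hdrPath)
  lines <- readLines(hdrPath, warn = FALSE)
  hdrText <- paste(lines, collapse = "\n")
  getField <- function(name) {
    hit <- grep(paste0("^", name, "\\s*="), lines, value = TRUE,
                ignore.case = TRUE)
    if (!length(hit)) stop("readCube: malformed header, missing ", name)
    trimws(sub("^[^=]*=", "", hit[1]))
  }
  ns <- as.integer(getField("samples"))
  nl <- as.integer(getField("lines"))
  nb <- as.integer(getField("bands"))
  dt <- as.integer(getField("data type"))
  il <- tolower(getField("interleave"))
  if (is.na(ns) || is.na(nl) || is.na(nb))
    stop("readCube: malformed header dimensions")
  if (!dt %in% c(4L, 5L)) stop("readCube: unsupported data type ", dt)
  if (il != "bsq") stop("readCube: unsupported interleave ", il)
  wvm <- regmatches(hdrText,
    regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", hdrText))[[1]]
  if (length(wvm) < 2) stop("readCube: header lacks wavelengths")
  wv <- as.numeric(strsplit(wvm[2], ",")[[1]])
  if (anyNA(wv) || length(wv) != nb)
    stop("readCube: wavelength list length does not match bands")
  size <- if (dt == 5L) 8L else 4L
  n <- ns * nl * nb
  raw <- readBin(path, "numeric", n = n + 1L, size = size,
                 endian = "little")
  if (length(raw) != n)
    stop("readCube: binary size does not match header dimensions")
  bsq <- array(raw, c(ns, nl, nb))
  data <- aperm(bsq, c(2, 1, 3))
  maskPath <- paste0(path, ".mask")
  mask <- if (file.exists(maskPath)) {
    m <- as.matrix(utils::read.table(maskPath))
    if (!all(dim(m) == c(nl, ns)))
      stop("readCube: mask shape does not match image")
    matrix(as.logical(m), nl, ns)
  } else matrix(TRUE, nl, ns)
  metaLine <- grep("^; meta = ", lines, value = TRUE)
  mt <- if (length(metaLine))
    as.list(jsonlite::fromJSON(sub("^; meta = ", "", metaLine[1])))
  else list()
  setCubeMeta(HyperspectralCube(wv, data, mask), mt)
}

setCubeMeta <- function(cube, meta) {
  cube@meta <- meta
  cube
}

## ---- CSV spectra and reference tables ---------------------------------

#' Read a CSV table of spectra
#'
#' Layout: first column `sample_id`, optional `replicate` and `instrument`
#' columns, then one numeric column per wavenumber with the wavenumber as the
#' column header. Returns one [Spectrum-class] per row on a shared grid.
#'
#' @param path CSV file path.
#' @return list of [Spectrum-class] objects.
#' @export
readSpectraTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("readSpectraTable: missing sample_id column")
  metaCols <- intersect(c("sample_id", "replicate", "instrument"), names(df))
  wnCols <- setdiff(names(df), metaCols)
  wn <- suppressWarnings(as.numeric(wnCols))
  if (anyNA(wn))
    stop("readSpectraTable: non-numeric wavenumber column headers: ",
         paste(wnCols[is.na(wn)], collapse = ", "))
  vals <- as.matrix(df[, wnCols, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals))
    stop("readSpectraTable: non-numeric absorbance cells")
  lapply(seq_len(nrow(df)), function(i) {
    s <- Spectrum(wn, vals[i, ])
    s@meta <- as.list(df[i, metaCols, drop = FALSE])
    s
  })
}

#' Write spectra to a CSV table
#'
#' Inverse of [readSpectraTable()]; all spectra must share one grid.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectraTable <- function(spectra, path) {
  g <- wavenumbers(spectra[[1]])
  for (s in spectra)
    if (!isTRUE(all.equal(wavenumbers(s), g)))
      stop("writeSpectraTable: spectra must share one grid")
  metaOf <- function(s, k, default)
    if (is.null(s@meta[[k]])) default else as.character(s@meta[[k]])
  df <- data.frame(
    sample_id = vapply(spectra, metaOf, "", k = "sample_id", default = ""),
    replicate = vapply(spectra, metaOf, "", k = "replicate", default = "1"),
    instrument = vapply(spectra, metaOf, "", k = "instrument",
                        default = "macro"),
    check.names = FALSE)
  m <- do.call(rbind, lapply(spectra, absorbance))
  colnames(m) <- formatC(g, digits = 17, format = "g")
  utils::write.csv(cbind(df, as.data.frame(m, check.names = FALSE)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a reference-analysis table
#'
#' CSV with columns `sample_id`, `analyte`, `value`, `replicate`. Values are
#' percentages of biomass (or of total fatty acids for SFA/PFA) and must lie
#' in `[0, 100]`; sample ids must be unique per (analyte, replicate).
#'
#' @param path CSV file path.
#' @return a `data.frame` with the four columns, `value` numeric.
#' @export
readReferenceTable <- function(path) {
  df <- utils::read.csv(path)
  validateReferenceTable(df)
}

#' Validate a reference table
#'
#' @param df data.frame with columns `sample_id`, `analyte`, `value` and
#'   optionally `replicate` (default 1).
#' @return the validated data.frame.
#' @export
validateReferenceTable <- function(df) {
  need <- c("sample_id", "analyte", "value")
  if (!all(need %in% names(df)))
    stop("reference table: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(v))
    stop("reference table: non-numeric values")
  if (any(v < 0 | v > 100))
    stop("reference table: values must lie in [0, 100]")
  df$value <- v
  key <- paste(df$sample_id, df$analyte, df$replicate)
  if (anyDuplicated(key))
    stop("reference table: duplicate (sample_id, analyte, replicate) rows")
  df[, c("sample_id", "analyte", "value", "replicate")]
}

#' Write a reference table to CSV
#'
#' @param df reference data.frame (validated first).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeReferenceTable <- function(df, path) {
  utils::write.csv(validateReferenceTable(df), path, row.names = FALSE)
  invisible(path)
}
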