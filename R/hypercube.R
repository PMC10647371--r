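#' Construct a hyperspectral cube
#'
#' A hypercube is a 3-D raster with two spatial axes and one spectral axis:
#' `data[i, j, c]` holds the signal at scan line `i` (1..N), cross-track
#' pixel `j` (1..M) and band `c` (1..Lc). Raw cubes store digital counts;
#' calibrated cubes store reflectance (see [calibrate_reflectance()]).
#'
#' @param data numeric 3-D array, `N x M x Lc`, finite and nonnegative.
#' @param wavelengths strictly increasing numeric vector of band centers in
#'   nanometres, length `Lc`.
#' @param calibrated logical; `TRUE` when `data` holds reflectance.
#' @return An object of class `"hypercube"`.
#' @export
hypercube <- function(data, wavelengths, calibrated = FALSE) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array (lines x pixels x bands)")
  storage.mode(data) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("corrupt raster: wavelength axis length does not match band count")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (anyNA(data) || any(!is.finite(data)))
    stop("cube values must be finite")
  if (any(data < 0))
    stop("cube values must be nonnegative")
  structure(list(data = data, wavelengths = wavelengths,
                 calibrated = isTRUE(calibrated)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d pixels x %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              if (x$calibrated) "reflectance" else "raw counts"))
  invisible(x)
}

#' @export
dim.hypercube <- function(x) dim(x$data)

#' Nominal spectral axis of the instrument
#'
#' 281 evenly spaced band centers over 400-1000 nm, the VIS-NIR layout of a
#' 281-channel push-broom line-scan camera.
#'
#' @param n_bands number of band centers.
#' @param range wavelength range in nm.
#' @return Numeric vector of band centers.
#' @export
nominal_wavelengths <- function(n_bands = 281L, range = c(400, 1000)) {
  seq(range[1], range[2], length.out = n_bands)
}

#' Construct a white-reference frame
#'
#' A push-broom system sees the diffuse reflectance standard as a single
#' frame: one value per cross-track pixel and band. The frame is broadcast
#' along the scan axis when calibrating a cube.
#'
#' @param values numeric matrix `M x Lc` of nonnegative counts.
#' @param wavelengths band centers in nm, length `Lc`.
#' @return An object of class `"reference_frame"`.
#' @export
reference_frame <- function(values, wavelengths) {
  if (!is.matrix(values)) stop("'values' must be an M x Lc matrix")
  storage.mode(values) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (ncol(values) != length(wavelengths))
    stop("wavelength axis length does not match band count")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("reference values must be finite and nonnegative")
  structure(list(values = values, wavelengths = wavelengths),
            class = "reference_frame")
}

# ---- ENVI-style I/O ---------------------------------------------------------

.envi_dtypes <- list(
  `1` = list(what = "integer", size = 1L, signed = FALSE),
  `2` = list(what = "integer", size = 2L, signed = TRUE),
  `3` = list(what = "integer", size = 4L, signed = TRUE),
  `4` = list(what = "numeric", size = 4L, signed = TRUE),
  `5` = list(what = "numeric", size = 8L, signed = TRUE),
  `12` = list(what = "integer", size = 2L, signed = FALSE)
)

.parse_envi_header <- function(path) {
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  txt <- gsub("\r", "", txt, fixed = TRUE)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (!grepl("=", ln, fixed = TRUE)) { i <- i + 1L; next }
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (startsWith(val, "{")) {
      while (!grepl("\\}", val) && i < length(lines)) {
        i <- i + 1L
        val <- paste(val, trimws(lines[[i]]))
      }
      val <- gsub("[{}]", "", val)
    }
    out[[key]] <- trimws(val)
    i <- i + 1L
  }
  out
}

.envi_data_path <- function(header_path) {
  base <- sub("\\.hdr$", "", header_path)
  for (ext in c(".dat", ".raw", ".img", "")) {
    p <- paste0(base, ext)
    if (file.exists(p) && p != header_path) return(p)
  }
  stop("corrupt raster: no companion data file for ", header_path)
}

#' Read an ENVI-style hyperspectral cube
#'
#' Reads a `key = value` ENVI header (with a `wavelength = {...}` block) and
#' its companion flat binary raster (BIL, BIP or BSQ interleave,
#' little-endian). Integer rasters round-trip bit-exactly through
#' [write_envi()].
#'
#' @param header_path path to the `.hdr` file.
#' @return A [hypercube()].
#' @export
read_envi <- function(header_path) {
  if (!file.exists(header_path)) stop("header not found: ", header_path)
  h <- .parse_envi_header(header_path)
  need <- c("samples", "lines", "bands")
  if (!all(need %in% names(h))) stop("corrupt raster: header lacks dimensions")
  M <- as.integer(h[["samples"]]); N <- as.integer(h[["lines"]])
  Lc <- as.integer(h[["bands"]])
  if (is.null(h[["wavelength"]])) stop("no spectral axis in header")
  wl <- as.numeric(strsplit(h[["wavelength"]], ",")[[1]])
  if (length(wl) != Lc)
    stop("corrupt raster: ", length(wl), " wavelengths for ", Lc, " bands")
  dt <- .envi_dtypes[[h[["data type"]] %||% "5"]]
  if (is.null(dt)) stop("unsupported data type ", h[["data type"]])
  interleave <- tolower(h[["interleave"]] %||% "bsq")
  data_path <- .envi_data_path(header_path)
  n <- as.double(N) * M * Lc
  if (file.size(data_path) != n * dt$size)
    stop("corrupt raster: data file size does not match samples*lines*bands")
  con <- file(data_path, "rb"); on.exit(close(con))
  v <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = "little")
  arr <- switch(interleave,
    bsq = aperm(array(v, c(M, N, Lc)), c(2, 1, 3)),
    bil = aperm(array(v, c(M, Lc, N)), c(3, 1, 2)),
    bip = aperm(array(v, c(Lc, M, N)), c(3, 2, 1)),
    stop("unsupported interleave ", interleave))
  hypercube(arr, wl, calibrated = identical(h[["calibrated"]], "1"))
}

#' Write a hyperspectral cube as an ENVI-style header + raster pair
#'
#' @param cube a [hypercube()].
#' @param path output header path (`.hdr` appended if missing); the raster is
#'   written alongside with a `.dat` extension.
#' @param interleave one of `"bil"`, `"bip"`, `"bsq"`.
#' @param data_type ENVI numeric type code; 5 (64-bit float) by default so
#'   any cube round-trips losslessly.
#' @return The header path, invisibly.
#' @export
write_envi <- function(cube, path, interleave = c("bil", "bip", "bsq"),
                       data_type = 5L) {
  stopifnot(inherits(cube, "hypercube"))
  interleave <- match.arg(interleave)
  if (!grepl("\\.hdr$", path)) path <- paste0(path, ".hdr")
  dt <- .envi_dtypes[[as.character(data_type)]]
  if (is.null(dt)) stop("unsupported data type ", data_type)
  d <- dim(cube$data); N <- d[1]; M <- d[2]; Lc <- d[3]
  hdr <- c(
    "ENVI",
    "description = {pelagiscan export}",
    sprintf("samples = %d", M),
    sprintf("lines = %d", N),
    sprintf("bands = %d", Lc),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", data_type),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    sprintf("calibrated = %d", as.integer(cube$calibrated)),
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE, digits = 12),
                  collapse = ", ")))
  ok <- tryCatch({
    writeLines(hdr, path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write header to ", path)
  v <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  data_path <- sub("\\.hdr$", ".dat", path)
  con <- file(data_path, "wb"); on.exit(close(con))
  if (dt$what == "integer") v <- as.integer(round(v))
  writeBin(v, con, size = dt$size, endian = "little")
  invisible(path)
}

# ---- Reflectance calibration ------------------------------------------------

#' Calibrate raw counts to reflectance against a white-reference frame
#'
#' Divides each raw spectrum by the white-standard frame, pixel by pixel and
#' band by band: `S(i,j,c) = A(i,j,c) / R(j,c)`, with the reference broadcast
#' along the scan axis. Reference entries below `1e-6` of the frame maximum
#' are raised to that floor before dividing, guarding against dead pixels.
#'
#' @param raw an uncalibrated [hypercube()] of digital counts.
#' @param reference a [reference_frame()] with an identical wavelength axis.
#' @param clip clamp the result to `[0, 1]` (a near-perfect diffuse standard
#'   can make true reflectance exceed 1 slightly); on by default, turn off
#'   for diagnostics.
#' @return A calibrated [hypercube()] of reflectance; the input is unchanged.
#' @export
calibrate_reflectance <- function(raw, reference, clip = TRUE) {
  stopifnot(inherits(raw, "hypercube"), inherits(reference, "reference_frame"))
  if (raw$calibrated) stop("cube is already calibrated")
  if (length(raw$wavelengths) != length(reference$wavelengths) ||
      any(abs(raw$wavelengths - reference$wavelengths) > 1e-9))
    stop("wavelength mismatch between cube and reference")
  d <- dim(raw$data); N <- d[1]; M <- d[2]; Lc <- d[3]
  if (!all(dim(reference$values) == c(M, Lc)))
    stop("reference frame dimensions do not match cube cross-track/band axes")
  ref <- reference$values
  mx <- max(ref)
  if (mx <= 0) stop("degenerate reference: frame is all zero")
  eps <- 1e-6 * mx
  ref <- pmax(ref, eps)
  if (any(ref <= 0)) stop("degenerate reference")
  denom <- aperm(array(ref, c(M, Lc, N)), c(3, 1, 2))
  s <- raw$data / denom
  if (clip) s <- pmin(pmax(s, 0), 1)
  hypercube(s, raw$wavelengths, calibrated = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
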