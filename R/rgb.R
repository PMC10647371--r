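# RGB rendering: emulate a conventional RGB camera viewing the scene by
# projecting the hyperspectral bands onto the camera's coarser channels and
# weighting those by its per-channel spectral sensitivity.

#' Construct an 8-bit RGB image
#'
#' @param pixels integer array `H x W x 3` with values in 0..255.
#' @param provenance free-form provenance record.
#' @return Object of class `"rgb_image"`.
#' @export
rgb_image <- function(pixels, provenance = NULL) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array")
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || any(pixels < 0L) || any(pixels > 255L))
    stop("pixel values must be integers in [0, 255]")
  structure(list(pixels = pixels, provenance = provenance),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d x 3, 8-bit\n", d[1], d[2]))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)

#' Build the band-averaging projection matrix
#'
#' Maps `Lc` hyperspectral bands onto `LRGB` coarse camera channels: column
#' `i` puts weight `1/n_i` on each of the `n_i` hyperspectral band centers
#' falling inside camera interval `[center_i - width/2, center_i + width/2)`,
#' so projecting a spectrum averages it over each camera channel. Camera
#' channels that catch no hyperspectral band get a zero column and are
#' reported in the `empty_channels` attribute (with a warning).
#'
#' @param cube_wavelengths hyperspectral band centers in nm.
#' @param camera_centers camera channel centers in nm (e.g. 400, 410, ...,
#'   720 for a 33-channel, 10-nm model).
#' @param width channel width in nm.
#' @return Object of class `"projection_matrix"` with fields `weights`
#'   (`Lc x LRGB`), `centers`, `edges`.
#' @export
build_projection_matrix <- function(cube_wavelengths, camera_centers,
                                    width = 10) {
  cube_wavelengths <- as.numeric(cube_wavelengths)
  camera_centers <- as.numeric(camera_centers)
  Lc <- length(cube_wavelengths); LRGB <- length(camera_centers)
  lo <- camera_centers - width / 2
  hi <- camera_centers + width / 2
  if (max(hi) <= min(cube_wavelengths) || min(lo) > max(cube_wavelengths))
    stop("disjoint spectral ranges")
  w <- matrix(0, Lc, LRGB)
  for (i in seq_len(LRGB)) {
    inside <- cube_wavelengths >= lo[i] & cube_wavelengths < hi[i]
    n <- sum(inside)
    if (n > 0) w[inside, i] <- 1 / n
  }
  empty <- which(colSums(w) == 0)
  if (length(empty))
    warning("camera channels with no hyperspectral band: ",
            paste(empty, collapse = ", "))
  if (all(colSums(w) == 0)) stop("disjoint spectral ranges")
  structure(list(weights = w, centers = camera_centers,
                 edges = c(lo, hi[LRGB]), empty_channels = empty),
            class = "projection_matrix")
}

#' Load a camera spectral-sensitivity table
#'
#' Expects a CSV with columns `wavelength_nm, R, G, B`: one row per camera
#' channel, nonnegative relative responses. The bundled
#' `canon_like_33band.csv` fixture is a synthetic 33-channel stand-in with
#' Gaussian channel responses (B, G, R centered at 460, 530, 600 nm, sigma
#' 30 nm); any table with the same schema is accepted.
#'
#' @param path CSV path.
#' @return Object of class `"sensitivity_matrix"` with fields `response`
#'   (`LRGB x 3`) and `wavelengths` (channel centers).
#' @export
load_sensitivity <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "R", "G", "B")
  if (!all(need %in% names(df)))
    stop("sensitivity CSV must have columns wavelength_nm, R, G, B")
  if (nrow(df) < 2L) stop("sensitivity table needs at least 2 rows")
  resp <- as.matrix(df[, c("R", "G", "B")])
  if (anyNA(resp) || any(resp < 0)) stop("negative sensitivity response")
  if (any(colSums(resp) == 0)) stop("a channel has all-zero response")
  structure(list(response = resp, wavelengths = df$wavelength_nm),
            class = "sensitivity_matrix")
}

#' Synthetic Gaussian camera sensitivity model
#'
#' Generates the same table shape as [load_sensitivity()] from Gaussian
#' channel responses; used to create the bundled fixture.
#'
#' @param centers camera channel centers in nm.
#' @param peak per-channel response peaks in nm, `c(R, G, B)`.
#' @param sigma Gaussian width in nm.
#' @return A `data.frame` with columns `wavelength_nm, R, G, B`.
#' @export
default_sensitivity_table <- function(centers = seq(400, 720, by = 10),
                                      peak = c(R = 600, G = 530, B = 460),
                                      sigma = 30) {
  g <- function(mu) exp(-0.5 * ((centers - mu) / sigma)^2)
  data.frame(wavelength_nm = centers,
             R = g(peak[["R"]]), G = g(peak[["G"]]), B = g(peak[["B"]]))
}

#' Render an RGB image from a hyperspectral cube
#'
#' Reshapes the cube to `(N*M) x Lc`, multiplies by the projection matrix
#' (`-> (N*M) x LRGB`) and by the sensitivity matrix (`-> (N*M) x 3`), then
#' reshapes back to `N x M x 3` and quantizes to 8 bits. Default scaling
#' divides by the maximum linear channel value of the image ("max"
#' normalization, deterministic); `scaling = "fixed"` multiplies by `gain`
#' instead and clips, for cross-image comparability.
#'
#' @param cube a [hypercube()] with `Lc` matching the projection rows.
#' @param proj a [build_projection_matrix()] result.
#' @param sens a [load_sensitivity()] result with `LRGB` rows.
#' @param scaling `"max"` or `"fixed"`.
#' @param gain linear gain for `scaling = "fixed"`.
#' @return An [rgb_image()] with `H = N`, `W = M`.
#' @export
render_rgb <- function(cube, proj, sens, scaling = c("max", "fixed"),
                       gain = 1) {
  stopifnot(inherits(cube, "hypercube"), inherits(proj, "projection_matrix"),
            inherits(sens, "sensitivity_matrix"))
  scaling <- match.arg(scaling)
  d <- dim(cube$data)
  if (d[3] != nrow(proj$weights) ||
      ncol(proj$weights) != nrow(sens$response))
    stop("projection/sensitivity incompatible with cube dimensions")
  lin <- matrix(cube$data, d[1] * d[2], d[3]) %*% proj$weights %*% sens$response
  if (scaling == "max") {
    m <- max(lin)
    px <- if (m <= 0) lin * 0 else lin / m
  } else {
    px <- pmin(pmax(lin * gain, 0), 1)
  }
  q <- as.integer(floor(px * 255 + 0.5)) # round half-up
  rgb_image(array(q, c(d[1], d[2], 3L)),
            provenance = list(scaling = scaling, gain = gain))
}

#' Write an RGB image as PNG
#'
#' @param img an [rgb_image()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_rgb_png <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}
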