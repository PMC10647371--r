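# Spectral signatures: per-fish averaged reflectance curves, either over the
# whole body mask or over randomly drawn regions of interest (RoIs). RoI
# averaging doubles as spectral data augmentation: two different RoI draws
# from the same fish give two slightly different signatures.

#' Construct a spectral signature
#'
#' @param values reflectance values, length `Lc'`.
#' @param wavelengths band centers in nm, same length.
#' @param provenance free-form provenance tag (sample id, RoI seed, ...).
#' @return Object of class `"spectral_signature"`.
#' @export
spectral_signature <- function(values, wavelengths, provenance = NULL) {
  values <- as.numeric(values); wavelengths <- as.numeric(wavelengths)
  if (length(values) != length(wavelengths))
    stop("values and wavelengths must have the same length")
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  structure(list(values = values, wavelengths = wavelengths,
                 provenance = provenance),
            class = "spectral_signature")
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat(sprintf("<spectral_signature> %d bands (%.0f-%.0f nm), mean %.3f\n",
              length(x$values), min(x$wavelengths), max(x$wavelengths),
              mean(x$values)))
  invisible(x)
}

#' Whole-body average reflectance of one fish
#'
#' Per band, the arithmetic mean of reflectance over the fish pixels. By
#' default only mask pixels contribute, so the board background cannot
#' contaminate the curve; `include_background = TRUE` averages over the full
#' crop instead (every pixel of the `N x M` window).
#'
#' @param fish_cube a calibrated [hypercube()] (typically a [crop_fish()]
#'   sub-cube).
#' @param mask a [fish_mask()] aligned to `fish_cube`.
#' @param include_background average over all crop pixels, not just the mask.
#' @return A [spectral_signature()] with `Lc' = Lc`.
#' @export
whole_body_signature <- function(fish_cube, mask, include_background = FALSE) {
  stopifnot(inherits(fish_cube, "hypercube"), inherits(mask, "fish_mask"))
  d <- dim(fish_cube$data)
  if (!all(dim(mask$mask) == d[1:2])) stop("mask does not match cube")
  if (!any(mask$mask)) stop("empty mask")
  mat <- matrix(fish_cube$data, d[1] * d[2], d[3])
  keep <- if (include_background) rep(TRUE, d[1] * d[2]) else as.vector(mask$mask)
  spectral_signature(colMeans(mat[keep, , drop = FALSE]),
                     fish_cube$wavelengths, provenance = "whole-body")
}

#' Draw random regions of interest inside a fish mask
#'
#' Each RoI is `P` distinct mask pixels drawn uniformly without replacement;
#' the RoIs need not be contiguous and different RoIs may overlap. Each RoI
#' uses its own RNG substream (subseeds pre-drawn from `seed`), so the r-th
#' RoI is reproducible regardless of how many are requested.
#'
#' @param mask a [fish_mask()].
#' @param R number of RoIs.
#' @param P pixels per RoI; must not exceed the mask area.
#' @param seed integer seed.
#' @return Object of class `"roi_set"`: a list of `R` two-column (row, col)
#'   1-based pixel coordinate matrices, plus the seed.
#' @export
sample_rois <- function(mask, R = 1L, P = 256L, seed = 1L) {
  stopifnot(inherits(mask, "fish_mask"), R >= 1L, P >= 1L)
  px <- which(mask$mask, arr.ind = TRUE)
  if (P > nrow(px)) stop("RoI larger than fish (P = ", P, ", mask area = ",
                         nrow(px), ")")
  rois <- with_seed(seed, {
    subseeds <- sample.int(.Machine$integer.max, R)
    lapply(seq_len(R), function(r)
      with_seed(subseeds[r], px[sample.int(nrow(px), P), , drop = FALSE]))
  })
  structure(list(rois = rois, seed = as.integer(seed), P = as.integer(P)),
            class = "roi_set")
}

#' Average spectral signatures over a set of RoIs
#'
#' Row `r` of the result is the per-band mean of the spectra of the `P`
#' pixels of RoI `r`; with `lc_prime` set, each averaged curve is then
#' resampled to that length (see [resample_signature()]), yielding the
#' `R x Lc'` signature array of one sample.
#'
#' @param fish_cube a calibrated [hypercube()].
#' @param rois a [sample_rois()] result with pixels inside the cube.
#' @param lc_prime optional reduced spectral length.
#' @param sample_id provenance tag.
#' @return Object of class `"signature_set"` with fields `signatures`
#'   (`R x Lc'` matrix), `wavelengths`, `sample_id`, `seed`.
#' @export
roi_signatures <- function(fish_cube, rois, lc_prime = NULL,
                           sample_id = NA_character_) {
  stopifnot(inherits(fish_cube, "hypercube"), inherits(rois, "roi_set"))
  d <- dim(fish_cube$data)
  mat <- matrix(fish_cube$data, d[1] * d[2], d[3])
  rows <- lapply(rois$rois, function(px) {
    if (any(px[, 1] < 1 | px[, 1] > d[1] | px[, 2] < 1 | px[, 2] > d[2]))
      stop("inconsistent RoI: pixel outside cube bounds")
    lin <- px[, 1] + (px[, 2] - 1L) * d[1]
    colMeans(mat[lin, , drop = FALSE])
  })
  wl <- fish_cube$wavelengths
  if (!is.null(lc_prime)) {
    rows <- lapply(rows, function(v)
      resample_signature(spectral_signature(v, wl), lc_prime)$values)
    wl <- seq(min(fish_cube$wavelengths), max(fish_cube$wavelengths),
              length.out = lc_prime)
  }
  structure(list(signatures = do.call(rbind, rows), wavelengths = wl,
                 sample_id = sample_id, seed = rois$seed),
            class = "signature_set")
}

#' Reduce a signature to a coarser spectral grid
#'
#' Linear interpolation onto `target_length` evenly spaced wavelengths
#' spanning the original range; the endpoints are preserved exactly.
#' Upsampling beyond the original band count is refused.
#'
#' @param sig a [spectral_signature()].
#' @param target_length desired length `Lc'` (2..`Lc`).
#' @return A [spectral_signature()] of length `target_length`.
#' @export
resample_signature <- function(sig, target_length) {
  stopifnot(inherits(sig, "spectral_signature"))
  n <- length(sig$values)
  if (target_length > n) stop("upsampling not allowed")
  if (target_length < 2L) stop("target_length must be at least 2")
  if (target_length == n) return(sig)
  xout <- seq(min(sig$wavelengths), max(sig$wavelengths),
              length.out = target_length)
  spectral_signature(stats::approx(sig$wavelengths, sig$values, xout)$y,
                     xout, provenance = sig$provenance)
}

#' Export signatures as CSV
#'
#' Single signatures are written long (`wavelength_nm,value`); signature
#' sets wide, one row per RoI with a header row of wavelengths.
#'
#' @param x a [spectral_signature()] or `signature_set`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_signature_csv <- function(x, path) {
  if (inherits(x, "spectral_signature")) {
    utils::write.csv(data.frame(wavelength_nm = x$wavelengths,
                                value = x$values), path, row.names = FALSE)
  } else if (inherits(x, "signature_set")) {
    m <- x$signatures
    colnames(m) <- format(x$wavelengths, trim = TRUE)
    utils::write.csv(m, path, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
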