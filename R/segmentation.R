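# Two-step isolation of individual fish from a calibrated multi-fish cube:
# threshold one high-contrast band, then label connected components and carry
# each component's bounding box through every band.

#' Construct a fish mask
#'
#' @param mask logical matrix (full scene, lines x pixels), `TRUE` on fish.
#' @param source_band 1-based index of the band the mask was derived from.
#' @return Object of class `"fish_mask"` with the mask, its tight bounding
#'   box (`bbox = c(row_min, row_max, col_min, col_max)`, 0-based half-open)
#'   and the source band.
#' @export
fish_mask <- function(mask, source_band = NA_integer_) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("empty mask")
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  structure(list(mask = mask,
                 bbox = c(row_min = min(rows) - 1L, row_max = max(rows),
                          col_min = min(cols) - 1L, col_max = max(cols)),
                 source_band = as.integer(source_band)),
            class = "fish_mask")
}

#' @export
print.fish_mask <- function(x, ...) {
  b <- x$bbox
  cat(sprintf("<fish_mask> %d px, bbox rows [%d,%d) cols [%d,%d), band %s\n",
              sum(x$mask), b[1], b[2], b[3], b[4], x$source_band))
  invisible(x)
}

# Otsu's criterion on a numeric vector: histogram the values and find the
# threshold maximizing the between-class variance. Returns the threshold and
# the criterion value (0 for a constant slice).
.otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(list(threshold = NA_real_, sigma_b = 0))
  bin <- pmin(nbins, 1L + as.integer((x - rng[1]) / (rng[2] - rng[1]) * nbins))
  p <- tabulate(bin, nbins) / length(x)
  mids <- rng[1] + (seq_len(nbins) - 0.5) * (rng[2] - rng[1]) / nbins
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mut <- mu0[nbins]
  sb <- (mut * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb) # first maximum -> lowest threshold on ties
  list(threshold = rng[1] + k * (rng[2] - rng[1]) / nbins, sigma_b = sb[k])
}

#' Pick the highest-contrast band for segmentation
#'
#' Scans every band of a calibrated cube and returns the (1-based) index of
#' the slice whose Otsu between-class variance is largest; this automates the
#' manual choice of a high-contrast wavelength. Ties break to the lowest
#' index.
#'
#' @param cube a calibrated [hypercube()].
#' @return Integer band index.
#' @export
choose_contrast_band <- function(cube) {
  stopifnot(inherits(cube, "hypercube"))
  Lc <- dim(cube$data)[3]
  sb <- vapply(seq_len(Lc),
               function(c) .otsu(as.vector(cube$data[, , c]))$sigma_b,
               numeric(1))
  if (all(sb == 0)) stop("no contrast in any band")
  which.max(sb)
}

#' Segment individual fish on one band
#'
#' Otsu-thresholds the chosen band slice, takes the minority class as
#' foreground, optionally bridges small gaps with a 3x3 morphological
#' closing, and returns each 8-connected component of at least `min_area`
#' pixels as a [fish_mask()], ordered left to right by bounding-box column.
#'
#' @param cube a calibrated [hypercube()].
#' @param band 1-based band index; `NULL` picks [choose_contrast_band()].
#' @param min_area minimum component area in pixels.
#' @param closing apply the 3x3 closing before labeling.
#' @return List of [fish_mask()] objects (possibly empty).
#' @export
segment_fish <- function(cube, band = NULL, min_area = 50L, closing = TRUE) {
  stopifnot(inherits(cube, "hypercube"))
  if (is.null(band)) band <- choose_contrast_band(cube)
  Lc <- dim(cube$data)[3]
  if (band < 1L || band > Lc) stop("band index out of range")
  slice <- cube$data[, , band]
  ot <- .otsu(as.vector(slice))
  if (ot$sigma_b == 0) stop("no contrast in selected band")
  fg <- slice > ot$threshold
  if (sum(fg) > length(fg) / 2) fg <- !fg # foreground is the minority class
  if (closing && any(fg)) {
    closed <- EBImage::closing(matrix(as.numeric(fg), nrow(fg)),
                               EBImage::makeBrush(3L, "box"))
    fg <- closed > 0.5
  }
  lab <- cpp_label8(fg)
  k <- max(lab)
  if (k == 0L) return(list())
  masks <- list()
  for (i in seq_len(k)) {
    m <- lab == i
    if (sum(m) >= min_area) masks[[length(masks) + 1L]] <- fish_mask(m, band)
  }
  ord <- order(vapply(masks, function(f) f$bbox[["col_min"]], numeric(1)),
               vapply(masks, function(f) f$bbox[["row_min"]], numeric(1)))
  masks[ord]
}

#' Crop one fish out of the scene across all bands
#'
#' Restricts the cube to the mask's bounding box in every band (the step the
#' segmentation repeats "through all the remaining wavelengths"). Background
#' pixels inside the box are retained but flagged by the returned mask.
#'
#' @param cube the [hypercube()] the mask was derived from.
#' @param fish a [fish_mask()].
#' @return List with `cube` (the sub-cube) and `mask` (a [fish_mask()]
#'   cropped to the same window).
#' @export
crop_fish <- function(cube, fish) {
  stopifnot(inherits(cube, "hypercube"), inherits(fish, "fish_mask"))
  d <- dim(cube$data)
  b <- fish$bbox
  if (!all(dim(fish$mask) == d[1:2]) ||
      b[["row_min"]] < 0 || b[["col_min"]] < 0 ||
      b[["row_max"]] > d[1] || b[["col_max"]] > d[2])
    stop("inconsistent mask")
  rows <- (b[["row_min"]] + 1L):b[["row_max"]]
  cols <- (b[["col_min"]] + 1L):b[["col_max"]]
  sub <- cube$data[rows, cols, , drop = FALSE]
  list(cube = hypercube(sub, cube$wavelengths, cube$calibrated),
       mask = fish_mask(fish$mask[rows, cols, drop = FALSE],
                        fish$source_band))
}

#' Export fish bounding boxes as a CSV table
#'
#' @param masks list of [fish_mask()] objects.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_bboxes_csv <- function(masks, path) {
  df <- do.call(rbind, lapply(seq_along(masks), function(i) {
    b <- masks[[i]]$bbox
    data.frame(fish_id = i, row_min = b[[1]], row_max = b[[2]],
               col_min = b[[3]], col_max = b[[4]],
               source_band = masks[[i]]$source_band)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a fish mask as an 8-bit PNG
#'
#' @param mask a [fish_mask()].
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}
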