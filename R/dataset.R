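# Labeled samples: each sample pairs a standardized 256x256 RGB image with a
# spectral signature of length Lc'. Images are held as 8-bit raw vectors (a
# 5000-sample set of doubles would not fit in memory) and may be stored
# lazily as augmentation recipes, to be materialized on demand.

.img_encode <- function(pixels) as.raw(pixels)

.img_decode <- function(rawv, size = 256L) {
  array(as.integer(rawv), c(size, size, 3L))
}

#' Construct a labeled sample dataset
#'
#' @param meta data frame with columns `id`, `label`, `kind`
#'   (`"provided"`/`"augmented"`), `source_id`, `aug_seed`, `roi_seed`.
#' @param images list of raw vectors (8-bit, `size*size*3` each) or `NULL`
#'   entries for lazily stored augmented images.
#' @param signatures numeric matrix, one row per sample, `Lc'` columns.
#' @param wavelengths signature wavelength axis, length `Lc'`.
#' @param classes character vector of class labels (the label universe).
#' @param banks named list (by provided-sample id) of masked-pixel spectra
#'   matrices used to redraw RoI signatures during balancing.
#' @param size image side length in pixels.
#' @return Object of class `"fish_dataset"`.
#' @export
fish_dataset <- function(meta, images, signatures, wavelengths,
                         classes = sort(unique(meta$label)), banks = NULL,
                         size = 256L) {
  stopifnot(is.data.frame(meta), nrow(meta) == length(images),
            nrow(meta) == nrow(signatures),
            ncol(signatures) == length(wavelengths))
  if (anyDuplicated(meta$id)) stop("sample ids must be unique")
  if (anyNA(signatures) || any(!is.finite(signatures)))
    stop("signatures must be finite")
  if (!all(meta$label %in% classes)) stop("label outside class set")
  structure(list(meta = meta, images = images, signatures = signatures,
                 wavelengths = as.numeric(wavelengths),
                 classes = as.character(classes), banks = banks,
                 size = as.integer(size)),
            class = "fish_dataset")
}

#' @export
print.fish_dataset <- function(x, ...) {
  cat(sprintf("<fish_dataset> %d samples, %d classes, Lc' = %d\n",
              nrow(x$meta), length(x$classes), ncol(x$signatures)))
  print(table(factor(x$meta$label, levels = x$classes)))
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds a [fish_dataset()].
#' @return Integer count.
#' @export
n_samples <- function(ds) nrow(ds$meta)

#' Subset a dataset by sample index
#' @param x a [fish_dataset()].
#' @param i integer or logical index vector.
#' @param ... unused.
#' @return A [fish_dataset()] with the selected samples.
#' @export
`[.fish_dataset` <- function(x, i, ...) {
  fish_dataset(x$meta[i, , drop = FALSE], x$images[i],
               x$signatures[i, , drop = FALSE], x$wavelengths,
               classes = x$classes, banks = x$banks, size = x$size)
}

#' Decode one sample's image to an integer array
#' @param ds a [fish_dataset()].
#' @param i sample index.
#' @return `size x size x 3` integer array (0..255).
#' @export
sample_image <- function(ds, i) {
  if (is.null(ds$images[[i]])) stop("image ", i, " not materialized")
  .img_decode(ds$images[[i]], ds$size)
}

#' Per-class sample counts
#' @param ds a [fish_dataset()].
#' @return Named integer vector over the class set.
#' @export
class_counts <- function(ds) {
  table(factor(ds$meta$label, levels = ds$classes))
}

# ---- Image standardization and augmentation ---------------------------------

.as_ebimage <- function(pixels) {
  EBImage::Image(array(pixels / 255, dim(pixels)), colormode = "Color")
}

.from_ebimage <- function(img) {
  v <- pmin(pmax(as.numeric(EBImage::imageData(img)), 0), 1)
  array(as.integer(floor(v * 255 + 0.5)), dim(EBImage::imageData(img)))
}

#' Standardize a fish crop to a fixed frame on white background
#'
#' Replaces every non-mask pixel by white, then bilinearly rescales to
#' `size x size` (aspect ratio not preserved, so an elongated crop is
#' stretched to the square frame). Idempotent on an already standardized
#' full-frame input.
#'
#' @param img an [rgb_image()] (any size).
#' @param mask a [fish_mask()] aligned to `img`; `NULL` keeps all pixels.
#' @param size output side length (default 256).
#' @return A `size x size` [rgb_image()].
#' @export
standardize_image <- function(img, mask = NULL, size = 256L) {
  stopifnot(inherits(img, "rgb_image"))
  px <- img$pixels
  d <- dim(px)
  if (d[1] == 0 || d[2] == 0) stop("empty image")
  if (!is.null(mask)) {
    if (!all(dim(mask$mask) == d[1:2])) stop("mask does not match image")
    bg <- !mask$mask
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[bg] <- 255L
      px[, , ch] <- plane
    }
  }
  if (d[1] != size || d[2] != size) {
    px <- .from_ebimage(EBImage::resize(.as_ebimage(px), w = size, h = size,
                                        filter = "bilinear"))
  }
  rgb_image(px, provenance = list(op = "standardize", from = d[1:2]))
}

#' Augmentation parameter ranges
#'
#' @param rotation max absolute rotation in degrees (uniform draw).
#' @param translation max absolute translation as a fraction of the frame
#'   per axis (uniform draw).
#' @param flip_h,flip_v allow horizontal/vertical flips (each with
#'   probability 0.5).
#' @return A list of ranges for [augment_image()].
#' @export
aug_ranges <- function(rotation = 25, translation = 0.1,
                       flip_h = TRUE, flip_v = TRUE) {
  list(rotation = rotation, translation = translation,
       flip_h = flip_h, flip_v = flip_v)
}

#' Randomly flip, rotate and translate a standardized image
#'
#' Applies, in order: horizontal flip (p = 0.5), vertical flip (p = 0.5),
#' rotation uniform in +/- `rotation` degrees, translation uniform in
#' +/- `translation` of the frame per axis. Rotation and translation use
#' bilinear interpolation and fill exposed regions with white. The output
#' frame equals the input frame; the whole draw is determined by `seed`.
#'
#' @param img a standardized square [rgb_image()].
#' @param seed integer seed.
#' @param ranges an [aug_ranges()] list.
#' @return An [rgb_image()] of the same size.
#' @export
augment_image <- function(img, seed, ranges = aug_ranges()) {
  stopifnot(inherits(img, "rgb_image"))
  px <- img$pixels
  d <- dim(px)
  with_seed(seed, {
    do_h <- isTRUE(ranges$flip_h) && stats::runif(1) < 0.5
    do_v <- isTRUE(ranges$flip_v) && stats::runif(1) < 0.5
    angle <- if (ranges$rotation > 0)
      stats::runif(1, -ranges$rotation, ranges$rotation) else 0
    shift <- if (ranges$translation > 0)
      round(stats::runif(2, -ranges$translation, ranges$translation) * d[1:2])
    else c(0, 0)
    if (do_h) px <- px[, d[2]:1, , drop = FALSE]
    if (do_v) px <- px[d[1]:1, , , drop = FALSE]
    if (angle != 0) {
      px <- .from_ebimage(EBImage::rotate(.as_ebimage(px), angle,
                                          filter = "bilinear",
                                          output.dim = d[1:2],
                                          bg.col = "white"))
    }
    if (any(shift != 0)) {
      px <- .from_ebimage(EBImage::translate(.as_ebimage(px), shift,
                                             filter = "bilinear",
                                             bg.col = "white"))
    }
    rgb_image(px, provenance = list(op = "augment", seed = seed,
                                    flips = c(do_h, do_v), angle = angle,
                                    shift = shift))
  })
}

# ---- Class balancing --------------------------------------------------------

# Redraw a fresh RoI signature for one source fish from its pixel bank.
.bank_signature <- function(bank, P, seed) {
  with_seed(seed, {
    n <- nrow(bank)
    take <- sample.int(n, min(P, n))
    colMeans(bank[take, , drop = FALSE])
  })
}

#' Balance a dataset by geometric + spectral augmentation
#'
#' Keeps every provided sample and tops each class up to `target_per_class`
#' by cycling through its originals: each augmented sample pairs a fresh
#' spatial transform of the source image ([augment_image()], fresh seed)
#' with a fresh RoI signature redrawn from the same source fish's pixel
#' bank. Augmentation never changes the label, and per class exactly
#' `target - n_provided` samples are added.
#'
#' @param originals a [fish_dataset()] of provided samples (with pixel
#'   banks for fresh signature draws).
#' @param target_per_class target count per class; at least the largest
#'   original class count.
#' @param seed integer seed; the whole balanced set is reproducible from it.
#' @param materialize_images decode/transform images now (`TRUE`) or record
#'   the recipe only (`FALSE`; see [materialize_images()]).
#' @param ranges [aug_ranges()] for the spatial transforms.
#' @param P pixels per redrawn RoI.
#' @return A balanced [fish_dataset()].
#' @export
balance_dataset <- function(originals, target_per_class, seed = 1L,
                            materialize_images = TRUE, ranges = aug_ranges(),
                            P = 256L) {
  stopifnot(inherits(originals, "fish_dataset"))
  counts <- class_counts(originals)
  if (any(counts == 0)) stop("cannot augment empty class: ",
                             paste(names(counts)[counts == 0], collapse = ", "))
  if (target_per_class < max(counts))
    stop("target_per_class below largest original class count")
  no_banks <- is.null(originals$banks)
  if (no_banks)
    warning("no pixel banks: augmented samples reuse source signatures")
  n_aug_total <- sum(target_per_class - counts)
  seeds <- with_seed(seed,
                     matrix(sample.int(.Machine$integer.max, 2L * n_aug_total),
                            nrow = 2L))
  meta_new <- list(); img_new <- list(); sig_new <- list()
  k <- 0L
  for (cl in originals$classes) {
    src <- which(originals$meta$label == cl)
    n_aug <- target_per_class - length(src)
    if (n_aug == 0L) next
    pick <- rep_len(src, n_aug) # cycle originals
    for (j in seq_len(n_aug)) {
      k <- k + 1L
      s <- pick[j]
      sid <- originals$meta$id[s]
      aug_seed <- seeds[1, k]; roi_seed <- seeds[2, k]
      meta_new[[k]] <- data.frame(
        id = sprintf("%s_a%03d", sid, j), label = cl, kind = "augmented",
        source_id = sid, aug_seed = aug_seed, roi_seed = roi_seed,
        stringsAsFactors = FALSE)
      img_new[k] <- list(
        if (materialize_images && !is.null(originals$images[[s]]))
          .img_encode(augment_image(
            rgb_image(sample_image(originals, s)), aug_seed, ranges)$pixels))
      sig_new[[k]] <- if (no_banks) originals$signatures[s, ]
      else .bank_signature(originals$banks[[sid]], P, roi_seed)
    }
  }
  meta0 <- originals$meta
  keep_cols <- c("id", "label", "kind", "source_id", "aug_seed", "roi_seed")
  for (col in keep_cols) if (is.null(meta0[[col]])) meta0[[col]] <- NA
  meta <- rbind(meta0[, keep_cols], do.call(rbind, meta_new))
  rownames(meta) <- NULL
  fish_dataset(meta, c(originals$images, img_new),
               rbind(originals$signatures, do.call(rbind, sig_new)),
               originals$wavelengths, classes = originals$classes,
               banks = originals$banks, size = originals$size)
}

#' Materialize lazily stored augmented images
#'
#' Fills every `NULL` image slot by re-running its recorded augmentation
#' recipe (source image + seed); a no-op for slots already present.
#'
#' @param ds a [fish_dataset()].
#' @param ranges the [aug_ranges()] used when balancing.
#' @return The dataset with all images present.
#' @export
materialize_images <- function(ds, ranges = aug_ranges()) {
  idx <- which(vapply(ds$images, is.null, logical(1)))
  if (!length(idx)) return(ds)
  lookup <- match(ds$meta$source_id[idx], ds$meta$id)
  for (j in seq_along(idx)) {
    i <- idx[j]; s <- lookup[j]
    if (is.na(s) || is.null(ds$images[[s]]))
      stop("source image missing for sample ", ds$meta$id[i])
    ds$images[[i]] <- .img_encode(augment_image(
      rgb_image(.img_decode(ds$images[[s]], ds$size)),
      ds$meta$aug_seed[i], ranges)$pixels)
  }
  ds
}

#' Write a dataset to disk (manifest + per-sample artifacts)
#'
#' Writes `manifest.csv` (id, label, kind, provenance, file names),
#' `signatures.csv` (wide, one row per sample) and one PNG per materialized
#' image.
#'
#' @param ds a [fish_dataset()].
#' @param dir output directory (created if needed).
#' @param images write PNGs too.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, images = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- ds$meta
  man$image_path <- ifelse(vapply(ds$images, is.null, logical(1)), NA,
                           file.path("images", paste0(man$id, ".png")))
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  sig <- as.data.frame(ds$signatures)
  names(sig) <- format(ds$wavelengths, trim = TRUE)
  utils::write.csv(cbind(id = man$id, sig), file.path(dir, "signatures.csv"),
                   row.names = FALSE)
  if (images) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    for (i in seq_len(nrow(man))) {
      if (is.null(ds$images[[i]])) next
      png::writePNG(sample_image(ds, i) / 255,
                    file.path(dir, "images", paste0(man$id[i], ".png")))
    }
  }
  invisible(dir)
}
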