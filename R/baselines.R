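# Classical baselines: histogram-of-oriented-gradients features and a
# linear support vector machine (one-vs-rest over e1071 binary machines)
# on several feature variants.

#' HOG descriptor parameters
#'
#' Defaults match the baseline configuration: 8 unsigned orientation bins,
#' 16x16-pixel cells, 4x4-cell blocks with one-cell stride and L2-Hys block
#' normalization. On a 256x256 frame this yields
#' `(16-4+1)^2 * 16 * 8 = 21,632` features.
#'
#' @param orientations number of unsigned orientation bins over `[0, 180)`.
#' @param pixels_per_cell cell side in pixels.
#' @param cells_per_block block side in cells.
#' @param clip L2-Hys clipping value.
#' @return Object of class `"hog_params"`.
#' @export
hog_params <- function(orientations = 8L, pixels_per_cell = 16L,
                       cells_per_block = 4L, clip = 0.2) {
  structure(list(orientations = as.integer(orientations),
                 pixels_per_cell = as.integer(pixels_per_cell),
                 cells_per_block = as.integer(cells_per_block), clip = clip),
            class = "hog_params")
}

#' Histogram-of-oriented-gradients features of a standardized image
#'
#' Converts to luminance (weights 0.299/0.587/0.114), takes centered-
#' difference gradients (zero at the frame border), accumulates magnitude-
#' weighted unsigned orientation histograms per cell, then concatenates
#' L2-Hys-normalized overlapping blocks. Constant images give an all-zero
#' vector (the normalization guard leaves zero blocks untouched).
#'
#' @param img an [rgb_image()] whose side is a multiple of the cell size.
#' @param p a [hog_params()].
#' @return Numeric feature vector.
#' @export
hog_features <- function(img, p = hog_params()) {
  stopifnot(inherits(img, "rgb_image"), inherits(p, "hog_params"))
  px <- img$pixels / 255
  H <- dim(px)[1]; W <- dim(px)[2]
  if (H %% p$pixels_per_cell != 0 || W %% p$pixels_per_cell != 0)
    stop("image side must be a multiple of the cell size")
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (g[, 3:W] - g[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (g[3:H, ] - g[1:(H - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180 # unsigned orientations
  nb <- p$orientations
  bin <- pmin(nb, 1L + as.integer(ang / (180 / nb)))
  cells_h <- H %/% p$pixels_per_cell
  cells_w <- W %/% p$pixels_per_cell
  ch <- 1L + (row(g) - 1L) %/% p$pixels_per_cell
  cw <- 1L + (col(g) - 1L) %/% p$pixels_per_cell
  # cell histograms: index (cell_h, cell_w, bin)
  idx <- ch + cells_h * (cw - 1L) + cells_h * cells_w * (bin - 1L)
  hist <- array(0, c(cells_h, cells_w, nb))
  acc <- tapply(as.vector(mag), as.vector(idx), sum)
  hist[as.integer(names(acc))] <- acc
  cb <- p$cells_per_block
  nbh <- cells_h - cb + 1L
  nbw <- cells_w - cb + 1L
  out <- numeric(nbh * nbw * cb * cb * nb)
  k <- 0L
  blk_len <- cb * cb * nb
  for (bw in seq_len(nbw)) for (bh in seq_len(nbh)) {
    v <- as.vector(hist[bh:(bh + cb - 1L), bw:(bw + cb - 1L), ])
    nrm <- sqrt(sum(v^2) + 1e-10)
    if (nrm > 1e-5) {
      v <- pmin(v / nrm, p$clip)
      v <- v / sqrt(sum(v^2) + 1e-10)
    }
    out[(k + 1L):(k + blk_len)] <- v
    k <- k + blk_len
  }
  out
}

# ---- Feature variants -------------------------------------------------------

#' Assemble baseline feature matrices from a dataset
#'
#' Variants: `"spectral"` (z-scored signatures), `"pixels"` (flattened
#' `[0,1]`-scaled image, width `size^2 * 3`), `"hog"` (HOG descriptor),
#' `"hog+spectral"` and `"pixels+spectral"` (column concatenation). Spectral
#' columns are standardized with training moments; pass the returned
#' `scaler` back in to transform held-out data consistently.
#'
#' @param ds a [fish_dataset()] with materialized images (image variants).
#' @param variant feature variant name.
#' @param p a [hog_params()] for the HOG variants.
#' @param scaler optional scaler from a previous (training) call.
#' @return List with `x` (feature matrix), `scaler`.
#' @export
baseline_features <- function(ds, variant = c("spectral", "pixels", "hog",
                                              "hog+spectral",
                                              "pixels+spectral"),
                              p = hog_params(), scaler = NULL) {
  variant <- match.arg(variant)
  parts <- list()
  if (variant %in% c("pixels", "pixels+spectral")) {
    parts$pixels <- t(.batch_spatial(ds, seq_len(n_samples(ds))))
  }
  if (variant %in% c("hog", "hog+spectral")) {
    parts$hog <- t(vapply(seq_len(n_samples(ds)), function(i)
      hog_features(rgb_image(sample_image(ds, i)), p),
      numeric(.hog_length(ds$size, p))))
  }
  if (variant %in% c("spectral", "hog+spectral", "pixels+spectral")) {
    s <- ds$signatures
    if (is.null(scaler)) {
      mu <- colMeans(s)
      sd <- apply(s, 2, stats::sd)
      sd[sd < 1e-12] <- 1
      scaler <- list(mean = mu, sd = sd)
    }
    parts$spectral <- sweep(sweep(s, 2, scaler$mean), 2, scaler$sd, "/")
  }
  list(x = do.call(cbind, parts), scaler = scaler)
}

.hog_length <- function(size, p) {
  cells <- size %/% p$pixels_per_cell
  (cells - p$cells_per_block + 1L)^2 * p$cells_per_block^2 * p$orientations
}

#' Train a one-vs-rest linear SVM
#'
#' Fits one binary linear SVM (default regularization, `C = 1`) per class
#' against the rest; prediction takes the class with the largest decision
#' value, ties breaking to the lowest class index.
#'
#' @param features numeric feature matrix, rows = samples.
#' @param labels class labels (character or factor).
#' @param kernel kernel name; only `"linear"` is supported.
#' @param cost regularization constant.
#' @return Object of class `"fish_svm"`.
#' @export
train_svm <- function(features, labels, kernel = "linear", cost = 1) {
  kernel <- match.arg(kernel, "linear")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  machines <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "rest"), levels = c("pos", "rest"))
    e1071::svm(features, y, kernel = "linear", cost = cost, scale = FALSE)
  })
  structure(list(machines = machines, classes = classes), class = "fish_svm")
}

#' @export
print.fish_svm <- function(x, ...) {
  cat(sprintf("<fish_svm> one-vs-rest linear SVM, %d classes\n",
              length(x$classes)))
  invisible(x)
}

#' Predict classes with a one-vs-rest linear SVM
#'
#' @param object a [train_svm()] fit.
#' @param newdata feature matrix with the training column layout.
#' @param type `"class"` or `"decision"` (per-class decision values).
#' @param ... unused.
#' @return Factor of labels or a decision-value matrix.
#' @export
predict.fish_svm <- function(object, newdata, type = c("class", "decision"),
                             ...) {
  type <- match.arg(type)
  dec <- vapply(seq_along(object$classes), function(k) {
    pr <- stats::predict(object$machines[[k]], newdata,
                         decision.values = TRUE)
    d <- drop(attr(pr, "decision.values"))
    # orient so larger means "this class"
    if (grepl("^pos/", colnames(attr(pr, "decision.values"))[1])) d else -d
  }, numeric(nrow(newdata)))
  dec <- matrix(dec, nrow = nrow(newdata))
  colnames(dec) <- object$classes
  if (type == "decision") return(dec)
  factor(object$classes[max.col(dec, ties.method = "first")],
         levels = object$classes)
}
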