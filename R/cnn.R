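# Two-channel convolutional classifier. The spatial channel runs two
# conv -> batch-norm -> ReLU -> 2x max-pool -> dropout stages over the
# 256x256x3 RGB image (8 then 16 filters, 3x3 kernels) and flattens to
# 64*64*16 = 65,536 features; the spectral channel runs the 1-D analogue
# (4 then 2 filters, length-5 kernels) over the length-Lc' signature and
# flattens to (Lc'/4)*2 features (100 at the default Lc' = 200). A dense
# head (64 ReLU units -> dropout -> softmax over the classes) consumes the
# concatenated features. Trained with plain SGD on cross-entropy.

#' CNN architecture configuration
#'
#' Defaults pin the architecture's two characteristic flatten sizes:
#' 65,536 spatial features for a 256x256x3 input and 100 spectral features
#' for a length-200 signature.
#'
#' @param input_size spatial input, `c(H, W, channels)`.
#' @param signature_length spectral input length `Lc'`; must survive two 2x
#'   poolings (divisible by 4).
#' @param n_classes number of output classes.
#' @param classes optional class labels (length `n_classes`).
#' @param spatial_filters filter counts of the two spatial conv layers.
#' @param spatial_kernel spatial kernel side (odd).
#' @param spectral_filters filter counts of the two spectral conv layers.
#' @param spectral_kernel spectral kernel length (odd).
#' @param pool pooling factor per stage (both channels).
#' @param dropout dropout probability after each pooling stage and in the
#'   head, in `[0, 1)`.
#' @param dense_units hidden units of the dense head.
#' @return Object of class `"cnn_config"`.
#' @export
cnn_config <- function(input_size = c(256L, 256L, 3L),
                       signature_length = 200L, n_classes = 5L,
                       classes = NULL, spatial_filters = c(8L, 16L),
                       spatial_kernel = 3L, spectral_filters = c(4L, 2L),
                       spectral_kernel = 5L, pool = 2L, dropout = 0.25,
                       dense_units = 64L) {
  if (signature_length %% (pool^2) != 0)
    stop("spectral length must survive two pools (divisible by ", pool^2, ")")
  if (any(input_size[1:2] %% (pool^2) != 0))
    stop("spatial input must survive two pools")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (spatial_kernel %% 2 != 1 || spectral_kernel %% 2 != 1)
    stop("kernels must be odd (same-size convolution)")
  if (!is.null(classes) && length(classes) != n_classes)
    stop("classes length must equal n_classes")
  structure(list(input_size = as.integer(input_size),
                 signature_length = as.integer(signature_length),
                 n_classes = as.integer(n_classes),
                 classes = classes,
                 spatial_filters = as.integer(spatial_filters),
                 spatial_kernel = as.integer(spatial_kernel),
                 spectral_filters = as.integer(spectral_filters),
                 spectral_kernel = as.integer(spectral_kernel),
                 pool = as.integer(pool), dropout = dropout,
                 dense_units = as.integer(dense_units)),
            class = "cnn_config")
}

# One conv -> bn+relu -> pool -> dropout block. H=1 makes it the 1-D case.
.init_block <- function(H, W, Cin, Cout, KH, KW, pool, dropout) {
  fan_in <- KH * KW * Cin
  list(conv = list(H = H, W = W, Cin = Cin, Cout = Cout, KH = KH, KW = KW,
                   Wt = matrix(stats::rnorm(fan_in * Cout, 0,
                                            sqrt(2 / fan_in)), fan_in, Cout),
                   b = numeric(Cout)),
       bn = list(C = Cout, gamma = rep(1, Cout), beta = numeric(Cout),
                 run_mean = numeric(Cout), run_var = rep(1, Cout),
                 eps = 1e-5, momentum = 0.1, seen = FALSE),
       pool = pool, dropout = dropout)
}

.init_dense <- function(n_in, n_out) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = numeric(n_out))
}

#' Build the two-channel CNN
#'
#' Constructs the (untrained, randomly initialized) network for one of the
#' three input regimes: `"spatial"` (RGB image only), `"spectral"`
#' (signature only) or `"fused"` (both channels, features concatenated).
#' Per-layer output shapes are queryable via [layer_shapes()].
#'
#' @param cfg a [cnn_config()].
#' @param mode input regime.
#' @return Object of class `"fishnet_arch"`.
#' @export
build_cnn <- function(cfg, mode = c("fused", "spatial", "spectral")) {
  stopifnot(inherits(cfg, "cnn_config"))
  mode <- match.arg(mode)
  p <- cfg$pool
  spatial <- spectral <- NULL
  n_feat <- 0L
  if (mode %in% c("fused", "spatial")) {
    H <- cfg$input_size[1]; W <- cfg$input_size[2]
    spatial <- list(
      .init_block(H, W, cfg$input_size[3], cfg$spatial_filters[1],
                  cfg$spatial_kernel, cfg$spatial_kernel, p, cfg$dropout),
      .init_block(H %/% p, W %/% p, cfg$spatial_filters[1],
                  cfg$spatial_filters[2], cfg$spatial_kernel,
                  cfg$spatial_kernel, p, cfg$dropout))
    n_feat <- n_feat + (H %/% p^2) * (W %/% p^2) * cfg$spatial_filters[2]
  }
  if (mode %in% c("fused", "spectral")) {
    L <- cfg$signature_length
    spectral <- list(
      .init_block(1L, L, 1L, cfg$spectral_filters[1], 1L,
                  cfg$spectral_kernel, p, cfg$dropout),
      .init_block(1L, L %/% p, cfg$spectral_filters[1],
                  cfg$spectral_filters[2], 1L, cfg$spectral_kernel, p,
                  cfg$dropout))
    n_feat <- n_feat + (L %/% p^2) * cfg$spectral_filters[2]
  }
  structure(list(cfg = cfg, mode = mode, spatial = spatial,
                 spectral = spectral, n_feat = n_feat,
                 dense1 = .init_dense(n_feat, cfg$dense_units),
                 dense2 = .init_dense(cfg$dense_units, cfg$n_classes)),
            class = "fishnet_arch")
}

.block_shapes <- function(blocks, in_shape) {
  out <- list()
  shape <- in_shape
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    shape <- c(shape[1], shape[2], b$conv$Cout)
    out[[length(out) + 1]] <- list(layer = sprintf("conv%d+bn+relu", i),
                                   shape = shape)
    pw <- b$pool
    shape <- c(if (shape[1] > 1) shape[1] %/% pw else 1L, shape[2] %/% pw,
               shape[3])
    out[[length(out) + 1]] <- list(layer = sprintf("pool%d+dropout", i),
                                   shape = shape)
  }
  out[[length(out) + 1]] <- list(layer = "flatten",
                                 shape = prod(shape))
  out
}

#' Query per-layer output shapes of a built network
#'
#' @param arch a [build_cnn()] result (or a trained `fishnet`).
#' @return A data frame with columns `channel`, `layer`, `shape` (printed
#'   `HxWxC`), `units` (total output size).
#' @export
layer_shapes <- function(arch) {
  if (inherits(arch, "fishnet")) arch <- arch$arch
  stopifnot(inherits(arch, "fishnet_arch"))
  rows <- list()
  add <- function(channel, layers) {
    for (l in layers)
      rows[[length(rows) + 1]] <<- data.frame(
        channel = channel, layer = l$layer,
        shape = paste(l$shape, collapse = "x"),
        units = prod(l$shape), stringsAsFactors = FALSE)
  }
  cfg <- arch$cfg
  if (!is.null(arch$spatial))
    add("spatial", .block_shapes(arch$spatial,
                                 c(cfg$input_size[1], cfg$input_size[2])))
  if (!is.null(arch$spectral))
    add("spectral", .block_shapes(arch$spectral,
                                  c(1L, cfg$signature_length)))
  rows[[length(rows) + 1]] <- data.frame(
    channel = "head", layer = "concat", shape = as.character(arch$n_feat),
    units = arch$n_feat, stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    channel = "head", layer = "dense+relu+dropout",
    shape = as.character(cfg$dense_units), units = cfg$dense_units,
    stringsAsFactors = FALSE)
  rows[[length(rows) + 1]] <- data.frame(
    channel = "head", layer = "dense+softmax",
    shape = as.character(cfg$n_classes), units = cfg$n_classes,
    stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Flattened feature length of one channel
#'
#' @param arch a [build_cnn()] result or trained `fishnet`.
#' @param channel `"spatial"` or `"spectral"`.
#' @return Integer number of flattened features, read from [layer_shapes()].
#' @export
flatten_units <- function(arch, channel = c("spatial", "spectral")) {
  channel <- match.arg(channel)
  sh <- layer_shapes(arch)
  row <- sh[sh$channel == channel & sh$layer == "flatten", ]
  if (nrow(row) == 0) stop("channel not present in this architecture")
  row$units
}

# ---- Forward / backward -----------------------------------------------------

.channel_forward <- function(blocks, X, training) {
  caches <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    cv <- b$conv
    Y <- cpp_conv2d_fw(X, cv$H, cv$W, cv$Cin, cv$Wt, cv$b, cv$KH, cv$KW)
    bn <- b$bn
    r <- cpp_bnpool_fw(Y, cv$H, cv$W, cv$Cout, bn$gamma, bn$beta, bn$eps,
                       training, bn$run_mean, bn$run_var,
                       if (cv$H > 1L) b$pool else 1L, b$pool)
    if (training) {
      # first batch seeds the running moments (no decay from the cold init)
      m <- if (bn$seen) bn$momentum else 1
      blocks[[i]]$bn$run_mean <- (1 - m) * bn$run_mean + m * r$mean
      blocks[[i]]$bn$run_var <- (1 - m) * bn$run_var + m * r$var
      blocks[[i]]$bn$seen <- TRUE
    }
    out <- r$y
    dmask <- NULL
    if (training && b$dropout > 0) {
      keep <- 1 - b$dropout
      dmask <- matrix((stats::runif(length(out)) < keep) / keep,
                      nrow(out), ncol(out))
      out <- out * dmask
    }
    caches[[i]] <- list(X = X, conv_out = Y, pool_idx = r$idx,
                        mean = r$mean, invstd = r$invstd, dmask = dmask)
    X <- out
  }
  list(out = X, caches = caches, blocks = blocks)
}

.channel_backward <- function(blocks, caches, dOut) {
  grads <- vector("list", length(blocks))
  for (i in rev(seq_along(blocks))) {
    b <- blocks[[i]]; cc <- caches[[i]]
    if (!is.null(cc$dmask)) dOut <- dOut * cc$dmask
    cv <- b$conv; bn <- b$bn
    r <- cpp_bnpool_bw(cc$conv_out, dOut, cc$pool_idx, cc$mean, cc$invstd,
                       bn$gamma, cv$H, cv$W, cv$Cout,
                       if (cv$H > 1L) b$pool else 1L, b$pool)
    cb <- cpp_conv2d_bw(cc$X, r$dX, cv$H, cv$W, cv$Cin, cv$Wt, cv$KH, cv$KW,
                        need_dx = i > 1L)
    grads[[i]] <- list(dW = cb$dW, db = cb$db, dgamma = r$dgamma,
                       dbeta = r$dbeta)
    dOut <- if (i > 1L) cb$dX else NULL
  }
  grads
}

.sgd_channel <- function(blocks, grads, lr, B) {
  for (i in seq_along(blocks)) {
    g <- grads[[i]]
    blocks[[i]]$conv$Wt <- blocks[[i]]$conv$Wt - lr * g$dW / B
    blocks[[i]]$conv$b <- blocks[[i]]$conv$b - lr * g$db / B
    blocks[[i]]$bn$gamma <- blocks[[i]]$bn$gamma - lr * g$dgamma / B
    blocks[[i]]$bn$beta <- blocks[[i]]$bn$beta - lr * g$dbeta / B
  }
  blocks
}

.softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

# Forward through the whole network. Returns probabilities plus everything
# the backward pass needs when training.
.net_forward <- function(arch, Xspat, Xspec, training) {
  feats <- list(); sp_fw <- sc_fw <- NULL
  if (!is.null(arch$spatial)) {
    sp_fw <- .channel_forward(arch$spatial, Xspat, training)
    arch$spatial <- sp_fw$blocks
    feats$spatial <- sp_fw$out
  }
  if (!is.null(arch$spectral)) {
    sc_fw <- .channel_forward(arch$spectral, Xspec, training)
    arch$spectral <- sc_fw$blocks
    feats$spectral <- sc_fw$out
  }
  F <- do.call(rbind, feats)
  Z1 <- crossprod(arch$dense1$W, F) + arch$dense1$b
  A1 <- pmax(Z1, 0)
  hmask <- NULL
  if (training && arch$cfg$dropout > 0) {
    keep <- 1 - arch$cfg$dropout
    hmask <- matrix((stats::runif(length(A1)) < keep) / keep,
                    nrow(A1), ncol(A1))
    A1 <- A1 * hmask
  }
  Z2 <- crossprod(arch$dense2$W, A1) + arch$dense2$b
  P <- .softmax_cols(Z2)
  list(arch = arch, P = P, F = F, Z1 = Z1, A1 = A1, hmask = hmask,
       sp_fw = sp_fw, sc_fw = sc_fw)
}

.net_backward_update <- function(arch, fw, y, lr) {
  B <- ncol(fw$P)
  dZ2 <- fw$P
  dZ2[cbind(y, seq_len(B))] <- dZ2[cbind(y, seq_len(B))] - 1
  dW2 <- fw$A1 %*% t(dZ2)
  db2 <- rowSums(dZ2)
  dA1 <- arch$dense2$W %*% dZ2
  if (!is.null(fw$hmask)) dA1 <- dA1 * fw$hmask
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- fw$F %*% t(dZ1)
  db1 <- rowSums(dZ1)
  dF <- arch$dense1$W %*% dZ1
  arch$dense2$W <- arch$dense2$W - lr * dW2 / B
  arch$dense2$b <- arch$dense2$b - lr * db2 / B
  arch$dense1$W <- arch$dense1$W - lr * dW1 / B
  arch$dense1$b <- arch$dense1$b - lr * db1 / B
  off <- 0L
  if (!is.null(arch$spatial)) {
    n <- nrow(fw$sp_fw$out)
    g <- .channel_backward(arch$spatial, fw$sp_fw$caches,
                           dF[seq_len(n), , drop = FALSE])
    arch$spatial <- .sgd_channel(arch$spatial, g, lr, B)
    off <- n
  }
  if (!is.null(arch$spectral)) {
    g <- .channel_backward(arch$spectral, fw$sc_fw$caches,
                           dF[(off + 1):nrow(dF), , drop = FALSE])
    arch$spectral <- .sgd_channel(arch$spectral, g, lr, B)
  }
  arch
}

# ---- Data plumbing ----------------------------------------------------------

.batch_spatial <- function(ds, idx) {
  n_in <- ds$size^2 * 3L
  m <- vapply(idx, function(i) {
    if (is.null(ds$images[[i]])) stop("image ", i, " not materialized")
    as.integer(ds$images[[i]])
  }, integer(n_in))
  matrix(m / 255, n_in, length(idx))
}

.batch_spectral <- function(ds, idx) {
  t(ds$signatures[idx, , drop = FALSE])
}

.eval_probs <- function(arch, ds, idx, batch_size = 64L) {
  P <- matrix(NA_real_, arch$cfg$n_classes, length(idx))
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / batch_size))) {
    Xs <- if (!is.null(arch$spatial)) .batch_spatial(ds, idx[s]) else NULL
    Xp <- if (!is.null(arch$spectral)) .batch_spectral(ds, idx[s]) else NULL
    P[, s] <- .net_forward(arch, Xs, Xp, training = FALSE)$P
  }
  P
}

.stratified_holdout <- function(labels, fraction, classes) {
  val <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(fraction * length(idx)))
    if (n_val >= length(idx)) n_val <- length(idx) - 1L
    if (n_val > 0) val <- c(val, sample(idx)[seq_len(n_val)])
  }
  sort(val)
}

#' Training configuration
#'
#' Defaults: plain SGD at learning rate 0.05, batch size 32, up to 4000
#' epochs with early stopping after 50 epochs without validation-loss
#' improvement, and 33% of the training data held out (stratified) for
#' validation.
#'
#' @param lr SGD learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience in epochs.
#' @param val_fraction stratified validation fraction of the training data.
#' @param seed integer seed controlling initialization, the validation
#'   split, shuffling and dropout.
#' @return Object of class `"train_config"`.
#' @export
train_config <- function(lr = 0.05, batch_size = 32L, epochs = 4000L,
                         patience = 50L, val_fraction = 0.33, seed = 1L) {
  stopifnot(lr > 0, batch_size >= 1, epochs >= 1, patience >= 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a built CNN on a labeled dataset
#'
#' Re-initializes the weights from `cfg$seed` (so a training run is fully
#' reproducible from the dataset and the training configuration alone),
#' splits off the stratified validation fraction, and minimizes
#' cross-entropy by minibatch SGD. Training stops early when the validation
#' loss has not improved for `patience` consecutive epochs; the
#' best-validation weights are restored.
#'
#' @param arch a [build_cnn()] architecture.
#' @param dataset a [fish_dataset()] with at least two classes present.
#' @param cfg a [train_config()].
#' @return A list with `model` (a trained `"fishnet"`) and `history`
#'   (per-epoch data frame of train/validation loss and accuracy).
#' @export
train_cnn <- function(arch, dataset, cfg = train_config()) {
  stopifnot(inherits(arch, "fishnet_arch"), inherits(dataset, "fish_dataset"),
            inherits(cfg, "train_config"))
  classes <- arch$cfg$classes %||% dataset$classes
  y_all <- match(dataset$meta$label, classes)
  if (anyNA(y_all)) stop("dataset labels outside model class set")
  if (length(unique(y_all)) < 2L) stop("need at least two classes to train")
  if (!is.null(arch$spectral) &&
      ncol(dataset$signatures) != arch$cfg$signature_length)
    stop("signature length does not match architecture")
  with_seed(cfg$seed, {
    arch <- build_cnn(arch$cfg, arch$mode) # fresh, seed-determined weights
    val <- .stratified_holdout(dataset$meta$label, cfg$val_fraction, classes)
    tr <- setdiff(seq_len(n_samples(dataset)), val)
    best <- list(loss = Inf, arch = arch, epoch = 0L)
    wait <- 0L
    hist <- list()
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(tr)
      tl <- 0; tn <- 0L; tc <- 0L
      for (bidx in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        Xs <- if (!is.null(arch$spatial)) .batch_spatial(dataset, bidx)
        Xp <- if (!is.null(arch$spectral)) .batch_spectral(dataset, bidx)
        fw <- .net_forward(arch, Xs, Xp, training = TRUE)
        arch <- fw$arch
        yb <- y_all[bidx]
        pl <- fw$P[cbind(yb, seq_along(bidx))]
        loss <- -sum(log(pmax(pl, 1e-12)))
        if (!is.finite(loss)) stop("NaN loss at epoch ", ep)
        tl <- tl + loss; tn <- tn + length(bidx)
        tc <- tc + sum(max.col(t(fw$P), ties.method = "first") == yb)
        arch <- .net_backward_update(arch, fw, yb, cfg$lr)
      }
      Pv <- .eval_probs(arch, dataset, val)
      pv <- Pv[cbind(y_all[val], seq_along(val))]
      vl <- -mean(log(pmax(pv, 1e-12)))
      if (!is.finite(vl)) stop("NaN validation loss at epoch ", ep)
      va <- mean(max.col(t(Pv), ties.method = "first") == y_all[val])
      hist[[ep]] <- data.frame(epoch = ep, train_loss = tl / tn,
                               train_acc = tc / tn, val_loss = vl,
                               val_acc = va)
      if (vl < best$loss - 1e-9) {
        best <- list(loss = vl, arch = arch, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    history <- do.call(rbind, hist)
    model <- structure(list(arch = best$arch, mode = arch$mode,
                            classes = classes, history = history,
                            best_epoch = best$epoch, train_config = cfg),
                       class = "fishnet")
    list(model = model, history = history)
  })
}

#' Fit the spatial-spectral fish classifier
#'
#' The single fitting entry point: builds the two-channel CNN for the
#' requested input regime and trains it on the dataset. Returns a fitted
#' model with `print`, `summary`, `predict` and `plot` methods.
#'
#' @param dataset a [fish_dataset()] of standardized images and signatures.
#' @param mode `"fused"`, `"spatial"` or `"spectral"`.
#' @param config a [cnn_config()]; by default derived from the dataset
#'   (class set, signature length, image size).
#' @param train a [train_config()].
#' @return A fitted `"fishnet"` object.
#' @examples
#' \dontrun{
#' ds <- generate_experiment(n_per_class = 20, seed = 1)
#' fit <- fishnet(ds, mode = "fused",
#'                train = train_config(epochs = 10, patience = 5, seed = 1))
#' predict(fit, ds[1:5])
#' }
#' @export
fishnet <- function(dataset, mode = c("fused", "spatial", "spectral"),
                    config = NULL, train = train_config()) {
  stopifnot(inherits(dataset, "fish_dataset"))
  mode <- match.arg(mode)
  if (is.null(config))
    config <- cnn_config(input_size = c(dataset$size, dataset$size, 3L),
                         signature_length = ncol(dataset$signatures),
                         n_classes = length(dataset$classes),
                         classes = dataset$classes)
  train_cnn(build_cnn(config, mode), dataset, train)$model
}

#' Predict species for new samples
#'
#' Dropout is disabled and batch norm uses its running moments, so
#' prediction is deterministic for a fixed fitted model. Probability ties
#' break to the lowest class index.
#'
#' @param object a fitted `"fishnet"`.
#' @param newdata a [fish_dataset()].
#' @param type `"class"` (factor of labels), `"prob"` (n x C probability
#'   matrix) or `"both"`.
#' @param ... unused.
#' @return Labels, probabilities, or both (see `type`).
#' @export
predict.fishnet <- function(object, newdata,
                            type = c("class", "prob", "both"), ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "fish_dataset"))
  P <- t(.eval_probs(object$arch, newdata, seq_len(n_samples(newdata))))
  colnames(P) <- object$classes
  labels <- factor(object$classes[max.col(P, ties.method = "first")],
                   levels = object$classes)
  switch(type, class = labels, prob = P,
         both = list(labels = labels, prob = P))
}

#' @export
print.fishnet <- function(x, ...) {
  cat(sprintf("<fishnet> mode=%s, %d classes, best epoch %d (val loss %.4f)\n",
              x$mode, length(x$classes), x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

#' @export
summary.fishnet <- function(object, ...) {
  cat("Spatial-spectral CNN fish classifier\n")
  cat("mode:", object$mode, " classes:",
      paste(object$classes, collapse = ", "), "\n")
  cat("epochs run:", nrow(object$history), " best epoch:",
      object$best_epoch, "\n")
  cat("final train acc:", round(utils::tail(object$history$train_acc, 1), 4),
      " best val acc:", round(max(object$history$val_acc), 4), "\n\n")
  print(layer_shapes(object$arch))
  invisible(object)
}

#' Plot training history
#'
#' Train and validation cross-entropy per epoch, with the best (restored)
#' epoch marked.
#'
#' @param x a fitted `"fishnet"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.fishnet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
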