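# Evaluation machinery: confusion-matrix metrics (one-vs-rest accuracy,
# precision, recall, F1, support-weighted averages), zero-one loss,
# stratified k-fold cross-validation, learning curves, and the paired
# Wilcoxon signed-rank comparison of per-sample losses.

#' Confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes label universe; defaults to the union of observed labels.
#' @return `C x C` integer matrix of class `"confusion_matrix"`; rows are
#'   true classes, columns predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (!all(c(y_true, y_pred) %in% classes))
    stop("label outside class set")
  cm <- table(factor(y_true, levels = classes),
              factor(y_pred, levels = classes))
  structure(unclass(as.matrix(cm)), class = "confusion_matrix")
}

#' Classification metrics from a confusion matrix
#'
#' Reduces each class one-vs-rest (`TP` on the diagonal, `FP` the rest of
#' its column, `FN` the rest of its row, `TN` everything else) and reports
#' per-class accuracy, precision, recall and F1 in percent, their
#' support-weighted averages, and the global accuracy (trace over total).
#' Support-weighted recall equals global accuracy algebraically — the reason
#' overall accuracy and recall columns coincide in weighted reporting.
#' Classes with zero support and zero predictions get 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @return Object of class `"metrics_report"`: list with `per_class` (data
#'   frame), `weighted` (named vector PRE/REC/F1), `accuracy` (global, %).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  if (any(tp + fp + fn == 0))
    warning("class with zero support and zero predictions; metrics set to 0")
  div <- function(a, b) ifelse(b == 0, 0, a / b)
  acc <- (tp + tn) / total
  pre <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  f1 <- div(2 * pre * rec, pre + rec)
  support <- rowSums(cm)
  w <- support / total
  structure(list(
    per_class = data.frame(class = classes, support = as.integer(support),
                           ACC = 100 * acc, PRE = 100 * pre, REC = 100 * rec,
                           F1 = 100 * f1, row.names = NULL),
    weighted = c(PRE = 100 * sum(w * pre), REC = 100 * sum(w * rec),
                 F1 = 100 * sum(w * f1)),
    accuracy = 100 * sum(tp) / total), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy %.2f%% | weighted PRE %.2f%% REC %.2f%% F1 %.2f%%\n",
              x$accuracy, x$weighted["PRE"], x$weighted["REC"],
              x$weighted["F1"]))
  print(x$per_class, digits = 4)
  invisible(x)
}

#' Zero-one loss
#'
#' Per-sample misclassification indicator and its mean; the mean equals
#' `1 - accuracy/100` on the same predictions.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return List with `losses` (0/1 vector) and `mean`.
#' @export
zero_one_loss <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  losses <- as.integer(as.character(y_true) != as.character(y_pred))
  list(losses = losses, mean = mean(losses))
}

# ---- Model specifications ---------------------------------------------------

#' Wrap a fit/predict pair for cross-validation
#'
#' @param fit `function(train_ds, seed)` returning a fitted object.
#' @param predict `function(fit, test_ds)` returning predicted labels.
#' @param label display name.
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(fit, predict, label = "model") {
  structure(list(fit = fit, predict = predict, label = label),
            class = "model_spec")
}

#' CNN model specification for cross-validation
#'
#' @param mode CNN input regime (see [fishnet()]).
#' @param train a [train_config()] (its seed is offset per fold).
#' @return A [model_spec()].
#' @export
model_spec_cnn <- function(mode = "fused", train = train_config()) {
  model_spec(
    fit = function(ds, seed) {
      tc <- train
      tc$seed <- as.integer(seed)
      fishnet(ds, mode = mode, train = tc)
    },
    predict = function(fit, ds) predict(fit, ds, type = "class"),
    label = paste0("CNN (", switch(mode, fused = "RGB + Spectral",
                                   spatial = "RGB", spectral = "Spectral"),
                   ")"))
}

#' Linear-SVM model specification for cross-validation
#'
#' @param variant feature variant (see [baseline_features()]).
#' @param p a [hog_params()].
#' @return A [model_spec()].
#' @export
model_spec_svm <- function(variant = "spectral", p = hog_params()) {
  label <- paste0("SVM (", switch(variant, spectral = "Spectral",
                                  pixels = "RGB", hog = "HOG",
                                  `hog+spectral` = "HOG + Spectral",
                                  `pixels+spectral` = "RGB + Spectral"), ")")
  model_spec(
    fit = function(ds, seed) {
      ft <- baseline_features(ds, variant, p)
      list(svm = train_svm(ft$x, ds$meta$label), scaler = ft$scaler,
           variant = variant, p = p)
    },
    predict = function(fit, ds) {
      ft <- baseline_features(ds, fit$variant, fit$p, scaler = fit$scaler)
      predict(fit$svm, ft$x)
    },
    label = label)
}

#' Majority-class dummy specification (for arithmetic checks)
#'
#' @return A [model_spec()] predicting the most frequent training label.
#' @export
model_spec_majority <- function() {
  model_spec(
    fit = function(ds, seed) names(which.max(table(ds$meta$label))),
    predict = function(fit, ds) rep(fit, n_samples(ds)),
    label = "majority")
}

# ---- Cross-validation -------------------------------------------------------

.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.grouped_folds <- function(groups, k) {
  g <- sample(unique(groups))
  gf <- rep_len(seq_len(k), length(g))
  gf[match(groups, g)]
}

#' Stratified k-fold cross-validation
#'
#' Assigns samples to `k` stratified folds (per-class round-robin after a
#' seeded shuffle, so fold class proportions stay within one sample of the
#' global proportions), then trains the model specification on `k - 1` folds
#' and evaluates on the held-out fold. With `group_by_source = TRUE`, all
#' augmented descendants of one physical fish share a fold (the
#' leakage-safe variant).
#'
#' @param dataset a [fish_dataset()].
#' @param k number of folds; every class must have at least `k` samples.
#' @param spec a [model_spec()].
#' @param seed integer seed (fold assignment and per-fold model seeds).
#' @param group_by_source group folds by `meta$source_id`.
#' @return Object of class `"cv_report"`: per-fold [metrics()], their means,
#'   pooled predictions with per-sample zero-one losses.
#' @export
kfold_cv <- function(dataset, k = 5L, spec, seed = 1L,
                     group_by_source = FALSE) {
  stopifnot(inherits(dataset, "fish_dataset"), inherits(spec, "model_spec"),
            k >= 2L)
  labels <- dataset$meta$label
  if (!group_by_source && any(table(labels) < k))
    stop("every class needs at least k samples")
  with_seed(seed, {
    fold <- if (group_by_source)
      .grouped_folds(dataset$meta$source_id %||% dataset$meta$id, k)
    else .stratified_folds(labels, k)
    fold_seeds <- sample.int(.Machine$integer.max, k)
    per_fold <- list(); pooled <- list()
    for (f in seq_len(k)) {
      test <- which(fold == f)
      train <- which(fold != f)
      fit <- spec$fit(dataset[train], fold_seeds[f])
      pred <- as.character(spec$predict(fit, dataset[test]))
      truth <- as.character(labels[test])
      cm <- confusion_matrix(truth, pred, classes = dataset$classes)
      per_fold[[f]] <- metrics(cm)
      pooled[[f]] <- data.frame(id = dataset$meta$id[test], fold = f,
                                true = truth, pred = pred,
                                loss = as.integer(truth != pred),
                                stringsAsFactors = FALSE)
    }
    pooled <- do.call(rbind, pooled)
    means <- c(Accuracy = mean(vapply(per_fold, `[[`, 1, "accuracy")),
               Precision = mean(vapply(per_fold,
                                       function(m) m$weighted[["PRE"]], 1)),
               Recall = mean(vapply(per_fold,
                                    function(m) m$weighted[["REC"]], 1)),
               F1 = mean(vapply(per_fold,
                                function(m) m$weighted[["F1"]], 1)))
    structure(list(label = spec$label, k = k, fold = fold,
                   per_fold = per_fold, mean_metrics = means,
                   pooled = pooled, seed = seed,
                   grouped = group_by_source),
              class = "cv_report")
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d-fold%s\n", x$label, x$k,
              if (x$grouped) " (grouped by source)" else ""))
  print(round(x$mean_metrics, 2))
  invisible(x)
}

#' Learning curve
#'
#' Splits off a stratified test set once, then for each requested training
#' size draws a seeded stratified subset of the training pool, fits the
#' model specification and records train and test zero-one error.
#'
#' @param spec a [model_spec()].
#' @param dataset a [fish_dataset()].
#' @param train_sizes ascending training-set sizes, at most the pool size.
#' @param seed integer seed.
#' @param test_fraction stratified held-out fraction.
#' @return Data frame `size, train_error, test_error` of class
#'   `"learning_curve"`.
#' @export
learning_curve <- function(spec, dataset, train_sizes, seed = 1L,
                           test_fraction = 0.25) {
  stopifnot(inherits(spec, "model_spec"), !is.unsorted(train_sizes))
  with_seed(seed, {
    test <- .stratified_holdout(dataset$meta$label, test_fraction,
                                dataset$classes)
    pool <- setdiff(seq_len(n_samples(dataset)), test)
    if (max(train_sizes) > length(pool))
      stop("training size exceeds available pool (", length(pool), ")")
    size_seeds <- sample.int(.Machine$integer.max, length(train_sizes))
    rows <- lapply(seq_along(train_sizes), function(i) {
      n <- train_sizes[i]
      sub <- with_seed(size_seeds[i], {
        # deal shuffled per-class queues round-robin, take the first n:
        # stratified at every prefix and equal to the whole pool at n = pool
        lbl <- dataset$meta$label[pool]
        queues <- lapply(split(seq_along(pool), lbl), sample)
        items <- unlist(queues, use.names = FALSE)
        depth <- unlist(lapply(queues, seq_along), use.names = FALSE)
        pool[items[order(depth)][seq_len(n)]]
      })
      fit <- spec$fit(dataset[sub], size_seeds[i])
      tr_err <- zero_one_loss(dataset$meta$label[sub],
                              spec$predict(fit, dataset[sub]))$mean
      te_err <- zero_one_loss(dataset$meta$label[test],
                              spec$predict(fit, dataset[test]))$mean
      data.frame(size = n, train_error = tr_err, test_error = te_err)
    })
    structure(do.call(rbind, rows), class = c("learning_curve", "data.frame"))
  })
}

# ---- Wilcoxon signed-rank ---------------------------------------------------

#' Paired Wilcoxon signed-rank comparison of per-sample losses
#'
#' Two-sided signed-rank test on the paired differences. Zero differences
#' are dropped (Wilcoxon's rule); ties among the remaining magnitudes get
#' midranks. For up to 25 effective pairs the p-value comes from the exact
#' sign-flip distribution of the positive-rank sum (all `2^n` assignments,
#' computed by convolution); beyond that, the normal approximation with tie
#' correction and continuity correction is used. All-zero differences give
#' `p = 1` with the `no_effect` flag.
#'
#' @param loss_a,loss_b equal-length per-sample loss vectors, paired by
#'   sample.
#' @param exact_max largest pair count handled exactly.
#' @return List with `statistic` (positive-rank sum `V`), `p.value`,
#'   `n_effective`, `method`, `no_effect`.
#' @export
wilcoxon_compare <- function(loss_a, loss_b, exact_max = 25L) {
  if (length(loss_a) != length(loss_b)) stop("length mismatch")
  d <- as.numeric(loss_a) - as.numeric(loss_b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p.value = 1, n_effective = 0L,
                method = "no effect", no_effect = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of the positive-rank sum over all sign flips;
    # doubled ranks keep midranks integral
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    pmf <- numeric(tot + 1L) # index = value + 1
    pmf[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), pmf[seq_len(tot + 1L - ri)])
      pmf <- (pmf + shifted) / 2
    }
    v2 <- round(2 * v)
    p_le <- sum(pmf[seq_len(v2 + 1L)])
    p_ge <- sum(pmf[(v2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact sign-flip distribution"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = v, p.value = p, n_effective = n, method = method,
       no_effect = FALSE)
}
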