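test_that("confusion matrix counts truth rows against prediction columns", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2,
                                   dimnames = dimnames(cm)),
               ignore_attr = TRUE)
  perfect <- confusion_matrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(sum(diag(perfect)), 3)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  expect_error(confusion_matrix(character(0), character(0)), "empty")
  expect_error(confusion_matrix("a", "z", classes = c("a", "b")),
               "outside the class set|outside class set")
})

test_that("metrics reproduce the one-vs-rest arithmetic", {
  # binary hand case: TP=50, FN=10, FP=10, TN=30 for the positive class
  cm <- structure(matrix(c(50L, 10L, 10L, 30L), 2, 2,
                         dimnames = list(c("pos", "neg"), c("pos", "neg"))),
                  class = "confusion_matrix")
  m <- metrics(cm)
  pos <- m$per_class[m$per_class$class == "pos", ]
  expect_equal(pos$ACC, 80)
  expect_equal(pos$PRE, 100 * 50 / 60)
  expect_equal(pos$REC, 100 * 50 / 60)
  expect_equal(pos$F1, 100 * 50 / 60) # harmonic mean of equal PRE/REC
  # diagonal matrix: everything 100%
  d <- confusion_matrix(rep(c("a", "b", "c"), 5), rep(c("a", "b", "c"), 5))
  md <- metrics(d)
  expect_equal(md$accuracy, 100)
  expect_equal(unname(md$weighted), c(100, 100, 100))
  expect_true(all(md$per_class[, c("ACC", "PRE", "REC", "F1")] == 100))
  # direct arithmetic oracle on a random multi-class table
  set.seed(7)
  yt <- sample(letters[1:4], 300, TRUE)
  yp <- ifelse(runif(300) < 0.6, yt, sample(letters[1:4], 300, TRUE))
  cm2 <- confusion_matrix(yt, yp, classes = letters[1:4])
  m2 <- metrics(cm2)
  for (k in 1:4) {
    tp <- cm2[k, k]; fp <- sum(cm2[, k]) - tp; fn <- sum(cm2[k, ]) - tp
    tn <- sum(cm2) - tp - fp - fn
    expect_equal(m2$per_class$ACC[k], 100 * (tp + tn) / sum(cm2))
    expect_equal(m2$per_class$PRE[k], 100 * tp / (tp + fp))
    expect_equal(m2$per_class$REC[k], 100 * tp / (tp + fn))
    pre <- tp / (tp + fp); rec <- tp / (tp + fn)
    expect_equal(m2$per_class$F1[k], 100 * 2 * pre * rec / (pre + rec))
  }
  # zero-support class warns and reports 0
  cm3 <- confusion_matrix(c("a", "a"), c("a", "a"), classes = c("a", "b"))
  expect_warning(m3 <- metrics(cm3), "zero support")
  expect_equal(m3$per_class$PRE[m3$per_class$class == "b"], 0)
})

test_that("accuracy, weighted recall and zero-one loss form one identity", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    classes <- letters[1:sample(2:6, 1)]
    yt <- sample(classes, n, TRUE)
    yp <- sample(classes, n, TRUE)
    m <- metrics(confusion_matrix(yt, yp, classes = classes))
    l <- zero_one_loss(yt, yp)
    expect_equal(m$accuracy, m$weighted[["REC"]])
    expect_equal(m$accuracy, 100 * (1 - l$mean))
    expect_equal(l$losses, as.integer(yt != yp))
  }
  expect_equal(zero_one_loss(1:4, 1:4)$mean, 0)
  expect_equal(zero_one_loss(1:4, c(2, 3, 4, 5))$mean, 1)
  expect_error(zero_one_loss(1:3, 1:4), "length mismatch")
})

test_that("stratified k-fold partitions the data with balanced classes", {
  ds <- toy_dataset(n_per_class = 12, n_classes = 3)
  r <- kfold_cv(ds, k = 4, model_spec_majority(), seed = 3)
  expect_equal(sort(r$pooled$id), sort(ds$meta$id)) # tested exactly once
  expect_equal(length(unique(r$pooled$fold)), 4)
  # per-fold class proportions within one sample of global
  for (f in 1:4) {
    idx <- which(r$fold == f)
    tt <- table(factor(ds$meta$label[idx], levels = ds$classes))
    expect_true(all(abs(tt - 3) <= 1))
  }
  # majority-class dummy on a balanced set: accuracy = 1/C per fold
  for (m in r$per_fold) expect_equal(m$accuracy, 100 / 3)
  expect_error(kfold_cv(toy_dataset(2, 2), k = 5, model_spec_majority()),
               "at least k samples")
  # grouped folds keep augmented descendants with their source
  ds2 <- small_dataset()
  # grouped folds may leave a fold without some class; the zero-support
  # guard warns, which is expected here
  rg <- suppressWarnings(kfold_cv(ds2, k = 3, model_spec_majority(),
                                  seed = 4, group_by_source = TRUE))
  fold_of <- rg$fold
  src_fold <- tapply(fold_of, ds2$meta$source_id,
                     function(v) length(unique(v)))
  expect_true(all(src_fold == 1))
})

test_that("learning curve tracks sizes and matches a plain evaluation", {
  ds <- toy_dataset(n_per_class = 16, n_classes = 2, lc = 12)
  spec <- model_spec_svm("spectral")
  sizes <- c(8, 24)
  lc <- learning_curve(spec, ds, sizes, seed = 5)
  expect_equal(nrow(lc), 2)
  expect_equal(lc$size, sizes)
  expect_true(all(lc$train_error >= 0 & lc$train_error <= 1))
  # separable data: test error at the largest size <= at the smallest
  expect_lte(lc$test_error[2], lc$test_error[1])
  expect_error(learning_curve(spec, ds, c(8, 1000), seed = 5),
               "exceeds")
})

test_that("Wilcoxon signed-rank matches enumeration and the reference test", {
  # all-equal losses: no effect
  r0 <- wilcoxon_compare(rep(1, 10), rep(1, 10))
  expect_equal(r0$p.value, 1)
  expect_true(r0$no_effect)
  # six nonzero same-sign differences: exact two-sided p = 2/2^6
  r6 <- wilcoxon_compare(c(1, 1, 1, 1, 1, 1), rep(0, 6))
  expect_equal(r6$p.value, 0.03125)
  expect_equal(r6$statistic, 21) # 1+2+...+6
  # statistic equals the explicit ranking oracle on random pairs
  set.seed(21)
  a <- runif(10); b <- runif(10)
  d <- a - b
  oracle_v <- sum(rank(abs(d))[d > 0])
  expect_equal(wilcoxon_compare(a, b)$statistic, oracle_v)
  # exact path agrees with the reference implementation (no ties, n = 12)
  a2 <- rnorm(12); b2 <- rnorm(12)
  ref <- stats::wilcox.test(a2, b2, paired = TRUE, exact = TRUE)
  got <- wilcoxon_compare(a2, b2)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value)
  # large-n path with heavy ties (0/1 losses) agrees with the normal
  # approximation with continuity and tie correction
  set.seed(22)
  la <- rbinom(80, 1, 0.5); lb <- rbinom(80, 1, 0.2)
  ref2 <- suppressWarnings(stats::wilcox.test(la, lb, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
  got2 <- wilcoxon_compare(la, lb)
  expect_equal(got2$statistic, unname(ref2$statistic))
  expect_equal(got2$p.value, ref2$p.value, tolerance = 1e-10)
  expect_equal(got2$method, "normal approximation with tie correction")
})
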