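test_that("constructed architecture reproduces the printed feature sizes", {
  cfg <- cnn_config() # 256x256x3 image, length-200 signature
  fused <- build_cnn(cfg, "fused")
  sh <- layer_shapes(fused)
  expect_equal(flatten_units(fused, "spatial"), 65536)
  expect_equal(flatten_units(fused, "spectral"), 100)
  expect_equal(fused$n_feat, 65636) # concatenation
  expect_equal(sh$units[sh$channel == "head" & sh$layer == "concat"], 65636)
  # the sizes come from shape propagation: a different Lc' moves them
  alt <- build_cnn(cnn_config(signature_length = 120), "spectral")
  expect_equal(flatten_units(alt, "spectral"), 60)
  # single-channel modes expose only their own flatten
  expect_error(flatten_units(build_cnn(cfg, "spatial"), "spectral"),
               "not present")
  # a spectral length that cannot survive two poolings is rejected
  expect_error(cnn_config(signature_length = 202),
               "survive two pools")
})

test_that("the fused conv-block kernel agrees with the stand-alone ones", {
  set.seed(17)
  H <- 8; W <- 12; C <- 3; B <- 5
  X <- matrix(rnorm(H * W * C * B), H * W * C, B)
  gamma <- runif(C, 0.5, 1.5); beta <- rnorm(C)
  fused <- pelagiscan:::cpp_bnpool_fw(X, H, W, C, gamma, beta, 1e-5, TRUE,
                                      numeric(C), rep(1, C), 2L, 2L)
  sep <- pelagiscan:::cpp_bnrelu_fw(X, H * W, C, gamma, beta, 1e-5, TRUE,
                                    numeric(C), rep(1, C))
  pooled <- pelagiscan:::cpp_maxpool_fw(sep$y, H, W, C, 2L, 2L)
  expect_equal(fused$y, pooled$y)
  expect_equal(fused$mean, sep$mean)
  expect_equal(fused$var, sep$var)
  # gradients agree between the fused backward and the chained backward
  dY <- matrix(rnorm(length(fused$y)), nrow(fused$y), B)
  fb <- pelagiscan:::cpp_bnpool_bw(X, dY, fused$idx, fused$mean,
                                   fused$invstd, gamma, H, W, C, 2L, 2L)
  dRelu <- pelagiscan:::cpp_maxpool_bw(dY, pooled$idx, nrow(sep$y))
  sb <- pelagiscan:::cpp_bnrelu_bw(dRelu, sep$xhat, H * W, C, gamma, beta,
                                   sep$invstd)
  expect_equal(fb$dX, sb$dX)
  expect_equal(fb$dgamma, sb$dgamma)
  expect_equal(fb$dbeta, sb$dbeta)
})

test_that("softmax output is a proper distribution over five classes", {
  cfg <- cnn_config(input_size = c(16L, 16L, 3L), signature_length = 16L)
  set.seed(1)
  arch <- build_cnn(cfg, "fused")
  Xs <- matrix(runif(16 * 16 * 3 * 20), ncol = 20)
  Xp <- matrix(runif(16 * 20), 16, 20)
  P <- pelagiscan:::.net_forward(arch, Xs, Xp, training = FALSE)$P
  expect_equal(dim(P), c(5, 20))
  expect_equal(unname(colSums(P)), rep(1, 20), tolerance = 1e-6)
  expect_true(all(P >= 0))
})

test_that("training drives a separable toy problem to zero training error", {
  ds <- toy_dataset(n_per_class = 12, n_classes = 3, size = 32L, lc = 16L)
  fit <- fishnet(ds, mode = "spectral",
                 train = train_config(epochs = 60, patience = 60,
                                      batch_size = 8, seed = 4))
  expect_lt(utils::tail(fit$history$train_loss, 1),
            fit$history$train_loss[1])
  # zero-one error on the training set reaches 0 within the epoch budget
  pred <- predict(fit, ds)
  expect_equal(zero_one_loss(ds$meta$label, pred)$mean, 0)
  # probability rows sum to one
  pr <- predict(fit, ds, type = "prob")
  expect_equal(unname(rowSums(pr)), rep(1, n_samples(ds)), tolerance = 1e-6)
})

test_that("early stopping halts after the patience window", {
  ds <- toy_dataset(n_per_class = 8, n_classes = 2, size = 16L, lc = 8L)
  # random labels: validation loss cannot keep improving for long
  set.seed(5)
  ds$meta$label <- sample(ds$meta$label)
  ds$signatures <- matrix(runif(length(ds$signatures)),
                          nrow(ds$signatures))
  fit <- fishnet(ds, mode = "spectral",
                 train = train_config(epochs = 400, patience = 5,
                                      batch_size = 8, seed = 6))
  h <- fit$history
  expect_lt(nrow(h), 400)
  # exactly `patience` non-improving epochs after the restored best epoch
  best <- which.min(h$val_loss)
  expect_equal(nrow(h), fit$best_epoch + 5)
})

test_that("training and prediction are seed-deterministic", {
  ds <- toy_dataset(n_per_class = 6, n_classes = 2, size = 16L, lc = 8L)
  tc <- train_config(epochs = 5, patience = 5, batch_size = 8, seed = 9)
  f1 <- fishnet(ds, mode = "fused", train = tc)
  f2 <- fishnet(ds, mode = "fused", train = tc)
  expect_identical(f1$history, f2$history)
  p1 <- predict(f1, ds, type = "prob")
  expect_identical(p1, predict(f1, ds, type = "prob"))
  f3 <- fishnet(ds, mode = "fused",
                train = train_config(epochs = 5, patience = 5,
                                     batch_size = 8, seed = 10))
  expect_false(identical(f1$history, f3$history))
})

test_that("argmax labeling breaks ties toward the lowest class index", {
  P <- rbind(c(0.1, 0.7, 0.1, 0.05, 0.05),
             c(0.5, 0.5, 0, 0, 0),
             c(0.2, 0.2, 0.2, 0.2, 0.2))
  classes <- paste0("c", 1:5)
  got <- classes[max.col(P, ties.method = "first")]
  expect_equal(got, c("c2", "c1", "c1"))
  # the same rule drives predict(): a fitted model picks column-1 on ties
  ds <- toy_dataset(n_per_class = 4, n_classes = 2, size = 16L, lc = 8L)
  fit <- fishnet(ds, mode = "spectral",
                 train = train_config(epochs = 2, patience = 2,
                                      batch_size = 4, seed = 1))
  both <- predict(fit, ds, type = "both")
  expect_equal(as.character(both$labels),
               fit$classes[max.col(both$prob, ties.method = "first")])
})

test_that("degenerate training inputs are rejected up front", {
  ds <- toy_dataset(n_per_class = 4, n_classes = 2, size = 16L, lc = 8L)
  bad <- ds$signatures
  bad[1, 1] <- Inf
  expect_error(fish_dataset(ds$meta, ds$images, bad, ds$wavelengths,
                            size = ds$size),
               "finite")
  one <- toy_dataset(n_per_class = 4, n_classes = 1, size = 16L, lc = 8L)
  expect_error(fishnet(one, mode = "spectral"), "two classes")
  # signature length must match the architecture
  arch <- build_cnn(cnn_config(input_size = c(16L, 16L, 3L),
                               signature_length = 12L, n_classes = 2L,
                               classes = c("class1", "class2")), "spectral")
  expect_error(train_cnn(arch, ds, train_config(epochs = 1)),
               "signature length")
})
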