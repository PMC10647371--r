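# Shared fixtures, built in code. Heavier objects are memoized so several
# test files can reuse one generation run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A deterministic raw cube with a simple closed form: value = i + 10*j + 100*c.
make_test_cube <- function(N = 4, M = 5, Lc = 3, calibrated = FALSE) {
  arr <- array(0, c(N, M, Lc))
  for (c in seq_len(Lc)) arr[, , c] <-
      outer(seq_len(N), seq_len(M), function(i, j) i + 10 * j) + 100 * c
  hypercube(arr, seq(400, 400 + 50 * (Lc - 1), by = 50),
            calibrated = calibrated)
}

# Small in-memory labeled dataset with random images and well-separated
# class signatures (class k peaks at a different band).
toy_dataset <- function(n_per_class = 10, n_classes = 3, size = 32L,
                        lc = 16L, seed = 42) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    n <- n_per_class * n_classes
    labels <- rep(paste0("class", seq_len(n_classes)), each = n_per_class)
    sig <- t(vapply(seq_len(n), function(i) {
      k <- (i - 1) %/% n_per_class + 1
      base <- 0.2 + 0.5 * exp(-((seq_len(lc) - 4 * k) / 2)^2)
      base + rnorm(lc, 0, 0.005)
    }, numeric(lc)))
    imgs <- lapply(seq_len(n), function(i) {
      k <- (i - 1) %/% n_per_class + 1
      base <- as.integer(pmin(255, pmax(0, 60 * k + rnorm(size * size * 3,
                                                          0, 12))))
      as.raw(base)
    })
    meta <- data.frame(id = sprintf("t%03d", seq_len(n)), label = labels,
                       kind = "provided", source_id = sprintf("t%03d",
                                                              seq_len(n)),
                       aug_seed = NA_integer_, roi_seed = NA_integer_,
                       stringsAsFactors = FALSE)
    fish_dataset(meta, imgs, sig, seq(400, 1000, length.out = lc),
                 size = size)
  })
}

# One small synthetic scene, reused across segmentation/signature tests.
small_scene <- function() memo("small_scene", {
  sc <- scene_spec(dims = c(160L, 240L), bands = 60L, fish_scale = 0.45,
                   seed = 7)
  generate_scene(sc)
})

small_calibrated <- function() memo("small_calibrated", {
  g <- small_scene()
  calibrate_reflectance(g$raw, g$reference)
})

# A small full-pipeline dataset (balanced, images materialized).
small_dataset <- function() memo("small_dataset", {
  sc <- scene_spec(dims = c(160L, 240L), bands = 60L, fish_scale = 0.45)
  generate_experiment(n_per_class = 12, originals_per_class = 3, scene = sc,
                      lc_prime = 40L, P = 128L, bank_px = 512L, seed = 21)
})

# Leakage-safe holdout: hold out a fraction of source fish per class, so
# augmented descendants of one physical fish never straddle the split.
grouped_holdout <- function(ds, frac, seed) {
  src <- unique(ds$meta$source_id)
  src_label <- ds$meta$label[match(src, ds$meta$id)]
  test_src <- pelagiscan:::with_seed(seed, unlist(lapply(
    split(src, src_label), function(v) sample(v, round(frac * length(v))))))
  which(ds$meta$source_id %in% test_src)
}

# Independent flood-fill labeling oracle (8-connected), recursive-free.
flood_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a < 1 || b < 1 || a > nrow(mask) || b > ncol(mask)) next
        if (mask[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- nxt
          stack[[length(stack) + 1]] <- c(a, b)
        }
      }
    }
  }
  lab
}
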