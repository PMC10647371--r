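# Independent Otsu criterion: brute-force scan over all candidate
# thresholds (midpoints of sorted unique values), maximizing the weighted
# between-class variance directly.
brute_otsu_sigma <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(0)
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- 0
  for (t in cand) {
    lo <- x[x <= t]; hi <- x[x > t]
    w0 <- length(lo) / length(x)
    s <- w0 * (1 - w0) * (mean(hi) - mean(lo))^2
    if (s > best) best <- s
  }
  best
}

test_that("contrast-band choice maximizes the between-class criterion", {
  set.seed(2)
  N <- 12; M <- 14; Lc <- 9
  arr <- array(0.5, c(N, M, Lc))
  fg <- matrix(FALSE, N, M); fg[4:8, 5:10] <- TRUE
  arr[, , 7][fg] <- 0.9
  arr[, , 7][!fg] <- 0.1
  arr[, , 3][fg] <- 0.55 # weaker contrast elsewhere
  arr[, , 3][!fg] <- 0.45
  cube <- hypercube(arr + array(abs(rnorm(N * M * Lc, 0, 1e-3)),
                                c(N, M, Lc)),
                    seq(400, 800, length.out = Lc), calibrated = TRUE)
  sb <- vapply(seq_len(Lc), function(c) brute_otsu_sigma(
    as.vector(cube$data[, , c])), numeric(1))
  expect_equal(choose_contrast_band(cube), which.max(sb))
  expect_equal(choose_contrast_band(cube), 7L)
  # single-band cube with contrast
  one <- hypercube(cube$data[, , 7, drop = FALSE], 400, calibrated = TRUE)
  expect_equal(choose_contrast_band(one), 1L)
  # all-constant cube has no contrast anywhere
  flat <- hypercube(array(0.5, c(4, 4, 3)), c(400, 500, 600),
                    calibrated = TRUE)
  expect_error(choose_contrast_band(flat), "no contrast")
})

test_that("two bright rectangles segment into two tight, ordered masks", {
  N <- 30; M <- 40
  slice <- matrix(0.1, N, M)
  slice[5:16, 4:13] <- 0.9   # 12 x 10 = 120 px, leftmost
  slice[20:27, 25:34] <- 0.9 # 8 x 10 = 80 px
  arr <- array(slice, c(N, M, 1))
  cube <- hypercube(arr, 550, calibrated = TRUE)
  masks <- segment_fish(cube, band = 1, min_area = 50, closing = FALSE)
  expect_length(masks, 2)
  expect_equal(unname(masks[[1]]$bbox), c(4, 16, 3, 13)) # 0-based half-open
  expect_equal(unname(masks[[2]]$bbox), c(19, 27, 24, 34))
  expect_equal(sum(masks[[1]]$mask), 120)
  expect_equal(sum(masks[[2]]$mask), 80)
  # agree with the flood-fill labeling oracle
  lab <- flood_label(slice > 0.5)
  expect_equal(masks[[1]]$mask, lab == lab[5, 4])
  expect_equal(masks[[2]]$mask, lab == lab[20, 25])
  # min_area filters: with min_area = 100 only the large one remains
  expect_length(segment_fish(cube, band = 1, min_area = 100,
                             closing = FALSE), 1)
  # sub-threshold specks yield an empty list, not an error
  tiny <- matrix(0.1, N, M); tiny[2:3, 2:3] <- 0.9
  empty <- segment_fish(hypercube(array(tiny, c(N, M, 1)), 550, TRUE),
                        band = 1, min_area = 50, closing = FALSE)
  expect_length(empty, 0)
  # a fully constant slice has no contrast
  expect_error(segment_fish(hypercube(array(0.2, c(N, M, 1)), 550, TRUE),
                            band = 1), "no contrast")
})

test_that("foreground polarity is the minority class and masks are disjoint", {
  N <- 30; M <- 30
  dark_fish <- matrix(0.9, N, M)
  dark_fish[10:15, 10:20] <- 0.1 # dark object on bright board
  cube <- hypercube(array(dark_fish, c(N, M, 1)), 550, TRUE)
  masks <- segment_fish(cube, band = 1, min_area = 20, closing = FALSE)
  expect_length(masks, 1)
  expect_equal(sum(masks[[1]]$mask), 6 * 11)
  # one large block (still the minority class) gets one tight bbox
  big <- matrix(0.1, 20, 20); big[2:10, 2:19] <- 0.9
  m <- segment_fish(hypercube(array(big, c(20, 20, 1)), 550, TRUE),
                    band = 1, min_area = 10, closing = FALSE)
  expect_length(m, 1)
  expect_equal(unname(m[[1]]$bbox), c(1, 10, 1, 19))
  # on the synthetic scene: pairwise disjoint, deterministic
  cal <- small_calibrated()
  d1 <- segment_fish(cal)
  d2 <- segment_fish(cal)
  expect_identical(d1, d2)
  acc <- matrix(0L, dim(cal)[1], dim(cal)[2])
  for (f in d1) acc <- acc + f$mask
  expect_true(all(acc <= 1L))
})

test_that("crop_fish windows every band and validates its mask", {
  cube <- make_test_cube(10, 10, 4, calibrated = TRUE)
  mask <- matrix(FALSE, 10, 10)
  mask[3:5, 4:7] <- TRUE # rows [2,5), cols [3,7) 0-based half-open
  fm <- fish_mask(mask)
  expect_equal(unname(fm$bbox), c(2, 5, 3, 7))
  cr <- crop_fish(cube, fm)
  expect_equal(dim(cr$cube$data), c(3, 4, 4))
  for (c in 1:4)
    expect_equal(cr$cube$data[, , c], cube$data[3:5, 4:7, c])
  expect_true(all(cr$mask$mask))
  # full-frame mask: identity crop
  full <- fish_mask(matrix(TRUE, 10, 10))
  expect_equal(crop_fish(cube, full)$cube$data, cube$data)
  # mask from another geometry is inconsistent
  expect_error(crop_fish(cube, fish_mask(matrix(TRUE, 3, 3))),
               "inconsistent mask")
})

test_that("cropping then re-segmenting returns the cropped mask", {
  # a thin diagonal object stays the minority class inside its own bbox
  N <- 40; M <- 40
  slice <- matrix(0.1, N, M)
  for (k in 5:30) slice[k + (-1:1), k] <- 0.9
  cube <- hypercube(array(slice, c(N, M, 1)), 550, TRUE)
  masks <- segment_fish(cube, band = 1, min_area = 20, closing = FALSE)
  expect_length(masks, 1)
  cr <- crop_fish(cube, masks[[1]])
  again <- segment_fish(cr$cube, band = 1, min_area = 20, closing = FALSE)
  expect_length(again, 1)
  expect_equal(again[[1]]$mask, cr$mask$mask)
})
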