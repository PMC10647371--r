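test_that("whole-body signature is the per-band mask mean", {
  # constant cube: signature constant at every band
  cube <- hypercube(array(0.42, c(6, 6, 5)), seq(400, 800, 100), TRUE)
  mask <- matrix(FALSE, 6, 6); mask[2:4, 3:5] <- TRUE
  sig <- whole_body_signature(cube, fish_mask(mask))
  expect_equal(sig$values, rep(0.42, 5))
  expect_equal(sig$wavelengths, cube$wavelengths)
  # one-pixel mask returns that pixel's spectrum
  m1 <- matrix(FALSE, 6, 6); m1[3, 4] <- TRUE
  set.seed(8)
  rnd <- hypercube(array(runif(6 * 6 * 5), c(6, 6, 5)),
                   seq(400, 800, 100), TRUE)
  expect_equal(whole_body_signature(rnd, fish_mask(m1))$values,
               as.numeric(rnd$data[3, 4, ]))
  # hand mean of two pixels
  two <- hypercube(array(0, c(2, 1, 2)), c(500, 600), TRUE)
  two$data[1, 1, ] <- c(0.2, 0.4); two$data[2, 1, ] <- c(0.6, 0.8)
  expect_equal(whole_body_signature(two, fish_mask(matrix(TRUE, 2, 1)))$values,
               c(0.4, 0.6))
  # brute-force pixel-loop oracle on a random cube and mask
  set.seed(9)
  mk <- matrix(runif(36) < 0.4, 6, 6); mk[1, 1] <- TRUE
  oracle <- numeric(5)
  for (c in 1:5) {
    s <- 0; n <- 0
    for (i in 1:6) for (j in 1:6) if (mk[i, j]) {
      s <- s + rnd$data[i, j, c]; n <- n + 1
    }
    oracle[c] <- s / n
  }
  expect_equal(whole_body_signature(rnd, fish_mask(mk))$values, oracle)
  # literal full-frame variant averages every crop pixel
  lit <- whole_body_signature(rnd, fish_mask(mk), include_background = TRUE)
  expect_equal(lit$values, apply(rnd$data, 3, mean))
})

test_that("RoI sampling is seed-reproducible and respects the mask", {
  mask <- matrix(FALSE, 8, 8); mask[2:6, 3:7] <- TRUE
  fm <- fish_mask(mask)
  # exhaustion: P = mask area gives the whole mask
  area <- sum(mask)
  rs <- sample_rois(fm, R = 1, P = area, seed = 1)
  px <- rs$rois[[1]]
  expect_equal(nrow(px), area)
  expect_equal(nrow(unique(px)), area)
  got <- matrix(FALSE, 8, 8); got[px] <- TRUE
  expect_equal(got, mask)
  expect_error(sample_rois(fm, R = 1, P = area + 1, seed = 1),
               "RoI larger than fish")
  # determinism and substream independence
  a <- sample_rois(fm, R = 3, P = 5, seed = 42)
  b <- sample_rois(fm, R = 3, P = 5, seed = 42)
  expect_identical(a$rois, b$rois)
  c3 <- sample_rois(fm, R = 3, P = 5, seed = 43)
  expect_false(identical(a$rois, c3$rois))
  # the r-th RoI does not depend on how many RoIs were requested
  expect_identical(sample_rois(fm, R = 1, P = 5, seed = 42)$rois[[1]],
                   a$rois[[1]])
  # all pixels inside the mask, no repeats within an RoI
  for (r in a$rois) {
    expect_true(all(mask[r]))
    expect_equal(nrow(unique(r)), 5)
  }
})

test_that("RoI signatures average the selected spectra (Eq.-style sum)", {
  set.seed(10)
  cube <- hypercube(array(runif(7 * 9 * 6), c(7, 9, 6)),
                    seq(400, 900, 100), TRUE)
  mask <- matrix(TRUE, 7, 9)
  fm <- fish_mask(mask)
  # P = 1: the row is that pixel's spectrum
  r1 <- sample_rois(fm, R = 1, P = 1, seed = 3)
  px <- r1$rois[[1]]
  expect_equal(as.numeric(roi_signatures(cube, r1)$signatures[1, ]),
               as.numeric(cube$data[px[1, 1], px[1, 2], ]))
  # R = 3, P = 4: direct summation oracle per RoI
  rs <- sample_rois(fm, R = 3, P = 4, seed = 5)
  ss <- roi_signatures(cube, rs)
  expect_equal(dim(ss$signatures), c(3, 6))
  for (r in 1:3) {
    oracle <- numeric(6)
    for (p in 1:4) {
      ij <- rs$rois[[r]][p, ]
      oracle <- oracle + as.numeric(cube$data[ij[1], ij[2], ])
    }
    expect_equal(as.numeric(ss$signatures[r, ]), oracle / 4)
  }
  # out-of-bounds RoI is inconsistent
  bad <- rs
  bad$rois[[1]][1, ] <- c(50, 50)
  expect_error(roi_signatures(cube, bad), "inconsistent RoI")
  # averaging bound: every value within the per-band pixel range
  mat <- matrix(cube$data, 63, 6)
  expect_true(all(ss$signatures >= matrix(apply(mat, 2, min), 3, 6,
                                          byrow = TRUE) - 1e-12))
  expect_true(all(ss$signatures <= matrix(apply(mat, 2, max), 3, 6,
                                          byrow = TRUE) + 1e-12))
})

test_that("one full-mask RoI reproduces the whole-body signature", {
  cal <- small_calibrated()
  masks <- segment_fish(cal)
  cr <- crop_fish(cal, masks[[1]])
  area <- sum(cr$mask$mask)
  rs <- sample_rois(cr$mask, R = 1, P = area, seed = 9)
  expect_equal(as.numeric(roi_signatures(cr$cube, rs)$signatures[1, ]),
               whole_body_signature(cr$cube, cr$mask)$values)
})

test_that("spectral resampling is linear interpolation with fixed endpoints", {
  wl <- nominal_wavelengths()
  # linear ramp stays a linear ramp under any target length
  ramp <- spectral_signature(seq(0.1, 0.9, length.out = 281), wl)
  for (n in c(200, 100, 20)) {
    rs <- resample_signature(ramp, n)
    expect_equal(rs$values, seq(0.1, 0.9, length.out = n))
    expect_equal(range(rs$wavelengths), range(wl))
  }
  # identity at target = Lc
  expect_identical(resample_signature(ramp, 281), ramp)
  # piecewise-linear curve: matches closed-form interpolation at each point
  # kink placed on a shared grid point (700 nm is the 141st of 281 centers
  # and also a point of every even resampling of the 400-1000 range)
  kink <- approxfun(c(400, 700, 1000), c(0.2, 0.8, 0.5))
  sig <- spectral_signature(kink(wl), wl)
  out <- resample_signature(sig, 200)
  expect_equal(out$values, kink(out$wavelengths))
  expect_error(resample_signature(sig, 300), "upsampling not allowed")
  expect_error(resample_signature(sig, 1), "at least 2")
  # signature set shape contract R x Lc'
  cube <- hypercube(array(runif(5 * 5 * 12), c(5, 5, 12)),
                    seq(400, 1000, length.out = 12), TRUE)
  rs <- sample_rois(fish_mask(matrix(TRUE, 5, 5)), R = 4, P = 6, seed = 2)
  ss <- roi_signatures(cube, rs, lc_prime = 8)
  expect_equal(dim(ss$signatures), c(4, 8))
})
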