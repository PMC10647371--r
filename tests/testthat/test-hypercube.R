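test_that("ENVI round-trip is lossless and preserves the wavelength axis", {
  cube <- hypercube(array(as.numeric(0:59), c(4, 5, 3)),
                    c(400, 500, 600))
  for (il in c("bil", "bip", "bsq")) {
    path <- file.path(tempdir(), paste0("rt_", il, ".hdr"))
    write_envi(cube, path, interleave = il)
    back <- read_envi(path)
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths, cube$wavelengths)
    expect_false(back$calibrated)
  }
  # 1x1x1 cube and calibrated flag survive
  one <- hypercube(array(7, c(1, 1, 1)), 550, calibrated = TRUE)
  p <- file.path(tempdir(), "one.hdr")
  write_envi(one, p)
  expect_equal(read_envi(p)$data[1, 1, 1], 7)
  expect_true(read_envi(p)$calibrated)
  # 2x2 cube with a long spectral axis round-trips elementwise
  set.seed(1)
  big <- hypercube(array(runif(2 * 2 * 281), c(2, 2, 281)),
                   nominal_wavelengths())
  p2 <- file.path(tempdir(), "big.hdr")
  write_envi(big, p2)
  expect_equal(read_envi(p2)$data, big$data)
})

test_that("interleaves agree with explicit index-arithmetic reordering", {
  set.seed(3)
  N <- 3; M <- 4; Lc <- 2
  cube <- hypercube(array(sample(0:999, N * M * Lc), c(N, M, Lc)),
                    c(500, 600))
  read_raw <- function(path) {
    con <- file(sub("hdr$", "dat", path), "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = N * M * Lc, size = 8, endian = "little")
  }
  pb <- file.path(tempdir(), "ord_bil.hdr")
  write_envi(cube, pb, interleave = "bil")
  v <- read_raw(pb)
  # BIL stores, for each scan line: all samples of band 1, band 2, ...
  oracle <- array(NA_real_, c(N, M, Lc))
  for (i in seq_len(N)) for (c in seq_len(Lc)) for (j in seq_len(M))
    oracle[i, j, c] <- v[(i - 1) * Lc * M + (c - 1) * M + j]
  expect_identical(oracle, cube$data)
  pp <- file.path(tempdir(), "ord_bip.hdr")
  write_envi(cube, pp, interleave = "bip")
  v <- read_raw(pp)
  # BIP stores every band of pixel (i, j) contiguously
  for (i in seq_len(N)) for (j in seq_len(M)) for (c in seq_len(Lc))
    oracle[i, j, c] <- v[((i - 1) * M + (j - 1)) * Lc + c]
  expect_identical(oracle, cube$data)
  # both interleaves read back to the same in-memory raster
  expect_identical(read_envi(pb)$data, read_envi(pp)$data)
})

test_that("corrupt or incomplete headers are rejected", {
  cube <- make_test_cube()
  p <- file.path(tempdir(), "bad.hdr")
  write_envi(cube, p)
  hdr <- readLines(p)
  # wavelength count disagreeing with bands
  writeLines(sub("wavelength = .*", "wavelength = {400, 450}", hdr), p)
  expect_error(read_envi(p), "corrupt raster")
  # missing spectral axis
  writeLines(hdr[!grepl("^wavelength =", hdr)], p)
  expect_error(read_envi(p), "no spectral axis")
  # truncated raster
  writeLines(hdr, p)
  dat <- sub("hdr$", "dat", p)
  writeBin(raw(10), dat)
  expect_error(read_envi(p), "corrupt raster")
})

test_that("hypercube and reference constructors enforce their invariants", {
  expect_error(hypercube(array(1, c(2, 2, 3)), c(400, 500)),
               "corrupt raster")
  expect_error(hypercube(array(1, c(2, 2, 2)), c(500, 400)),
               "strictly increasing")
  expect_error(hypercube(array(-1, c(1, 1, 1)), 500), "nonnegative")
  expect_error(reference_frame(matrix(1, 2, 3), c(400, 500)), "wavelength")
})

test_that("reflectance calibration matches the per-entry quotient", {
  # hand case: 2 lines x 2 pixels x 2 bands, reference varying by (j, c)
  A <- array(c(2, 1, 6, 3, 4, 2, 8, 4), c(2, 2, 2))
  R <- matrix(c(2, 2, 4, 4), 2, 2)
  raw <- hypercube(A, c(500, 600))
  ref <- reference_frame(R, c(500, 600))
  cal <- calibrate_reflectance(raw, ref, clip = FALSE)
  for (i in 1:2) for (j in 1:2) for (c in 1:2)
    expect_equal(cal$data[i, j, c], A[i, j, c] / R[j, c])
  expect_true(cal$calibrated)
  expect_false(raw$calibrated) # input untouched
  # larger brute-force oracle
  set.seed(5)
  A2 <- array(runif(6 * 7 * 4, 0, 100), c(6, 7, 4))
  R2 <- matrix(runif(7 * 4, 50, 150), 7, 4)
  cal2 <- calibrate_reflectance(hypercube(A2, c(1:4) * 100),
                                reference_frame(R2, c(1:4) * 100),
                                clip = FALSE)
  for (i in 1:6) for (j in 1:7) for (c in 1:4)
    expect_equal(cal2$data[i, j, c], A2[i, j, c] / R2[j, c])
})

test_that("self-calibration yields ones and scaling is equivariant", {
  set.seed(11)
  M <- 5; Lc <- 4
  R <- matrix(runif(M * Lc, 10, 100), M, Lc)
  wl <- seq(400, 700, length.out = Lc)
  broadcast <- aperm(array(R, c(M, Lc, 3)), c(3, 1, 2))
  cal <- calibrate_reflectance(hypercube(broadcast, wl),
                               reference_frame(R, wl), clip = FALSE)
  expect_equal(cal$data, array(1, c(3, M, Lc)))
  for (alpha in c(0, 0.3, 2)) {
    ca <- calibrate_reflectance(hypercube(alpha * broadcast, wl),
                                reference_frame(R, wl), clip = FALSE)
    expect_equal(ca$data, alpha * cal$data)
  }
})

test_that("calibration guards degenerate inputs and clips on request", {
  raw <- hypercube(array(4, c(2, 2, 2)), c(500, 600))
  expect_error(
    calibrate_reflectance(raw, reference_frame(matrix(1, 2, 2), c(500, 650))),
    "wavelength mismatch")
  expect_error(
    calibrate_reflectance(raw, reference_frame(matrix(0, 2, 2), c(500, 600))),
    "degenerate reference")
  ref <- reference_frame(matrix(2, 2, 2), c(500, 600))
  expect_equal(max(calibrate_reflectance(raw, ref, clip = TRUE)$data), 1)
  expect_equal(max(calibrate_reflectance(raw, ref, clip = FALSE)$data), 2)
})
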