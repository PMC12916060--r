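test_that("the default bank has 32 channels with doubling frequency", {
  bank <- tiny_bank()
  expect_equal(bank$n_channels, 32L)
  wl <- unique(bank$meta$wavelength)
  expect_equal(wl, 16 / 2^(0:3))
  # every kernel is exactly zero-sum
  for (k in bank$kernels) expect_lt(abs(sum(k)), 1e-10)
  expect_error(gabor_bank(base_wavelength = 8, n_frequencies = 4),
               "2 px")
})

test_that("uniform images produce zero response away from the border", {
  bank <- tiny_bank()
  f <- filter_image(matrix(0.7, 64, 64), bank)
  hs <- max(vapply(bank$kernels, nrow, 1L)) %/% 2L
  inner <- (hs + 1):(64 - hs)
  expect_lt(max(abs(f[inner, inner, ])), 1e-12)
  # the all-zero image is zero everywhere
  f0 <- filter_image(matrix(0, 64, 64), bank)
  expect_equal(max(abs(f0)), 0)
})

test_that("filtering matches a brute-force convolution oracle", {
  bank <- tiny_bank()
  set.seed(5)
  img <- matrix(runif(64 * 64) * 0.1, 64, 64)  # low contrast: no clipping
  signed <- filter_image(img, bank, rectify = FALSE)
  for (i in c(1, 6, 16)) {
    oracle <- naive_convolve(img, bank$kernels[[i]]) / bank$meta$norm[i]
    expect_equal(signed[, , i], oracle, tolerance = 1e-10)
  }
  # rectified P/N channels are the sign split of the same response
  f <- filter_image(img, bank)
  expect_equal(f[, , 1] - f[, , 2], signed[, , 1], tolerance = 1e-10)
})

test_that("orientation tuning: a vertical grating drives the 0-degree channel hardest", {
  bank <- tiny_bank()
  xs <- matrix(rep(seq_len(64), each = 64), 64, 64)
  grating <- 0.5 + 0.5 * cos(2 * pi * xs / 16)  # wavelength of band 0
  f <- filter_image(grating, bank)
  inner <- 21:44
  p0 <- max(f[inner, inner, 1])    # (f0, 0 deg, P)
  p90 <- max(f[inner, inner, 5])   # (f0, 90 deg, P)
  expect_gt(p0, p90)
  expect_equal(p0, 1, tolerance = 0.02)  # normalisation anchors peak at 1
})

test_that("filter responses stay in [0,1] and P/N channels are exclusive", {
  bank <- tiny_bank()
  f <- filter_image(tiny_set()$images[[1]], bank)
  expect_true(all(f >= 0 & f <= 1))
  for (i in seq_len(16))
    expect_equal(sum(f[, , 2 * i - 1] > 0 & f[, , 2 * i] > 0), 0)
})

test_that("negating an image swaps the P and N channels", {
  bank <- tiny_bank()
  img <- tiny_set()$images[[2]]
  f1 <- filter_image(img, bank)
  f2 <- filter_image(1 - img, bank)
  hs <- max(vapply(bank$kernels, nrow, 1L)) %/% 2L
  inner <- (hs + 1):(64 - hs)  # zero padding differs at the border
  for (i in seq_len(16)) {
    expect_equal(f1[inner, inner, 2 * i - 1], f2[inner, inner, 2 * i],
                 tolerance = 1e-10)
    expect_equal(f1[inner, inner, 2 * i], f2[inner, inner, 2 * i - 1],
                 tolerance = 1e-10)
  }
})

test_that("pre-rectification responses are linear in image contrast", {
  bank <- tiny_bank()
  set.seed(6)
  img <- matrix(runif(64 * 64) * 0.2, 64, 64)
  s1 <- filter_image(img, bank, rectify = FALSE)
  s3 <- filter_image(3 * img, bank, rectify = FALSE)
  expect_equal(s3, 3 * s1, tolerance = 1e-9)
})

test_that("byte storage quantises to 1/255 and dimension mismatches fail", {
  bank <- tiny_bank()
  fs <- tiny_filtered()
  full <- as.numeric(filter_image(tiny_set()$images[[1]], bank))
  expect_lt(max(abs(filtered_input_of(fs, 1) - full)), 1 / 500)
  fs2 <- filter_stimulus_set(tiny_set(), bank, storage = "double")
  expect_identical(filtered_input_of(fs2, 1), full)
  expect_error(filter_image(matrix(0, 32, 32), bank), "matching")
})
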