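test_that("generated sets have the right bookkeeping and determinism", {
  s <- generate_synthetic_objects(2, 1, size = 64, seed = 1)
  expect_length(s$images, 2)
  expect_equal(s$labels$object_id, c(0L, 1L))

  s2 <- generate_synthetic_objects(3, 4, size = 64, seed = 9)
  expect_equal(nrow(s2$labels), 12)
  expect_true(all(table(s2$labels$object_id) == 4))
  expect_true(all(vapply(s2$images, function(im)
    all(im >= 0 & im <= 1), TRUE)))

  # same seed twice -> bit-identical pixels
  s3 <- generate_synthetic_objects(3, 4, size = 64, seed = 9)
  expect_identical(s2$images, s3$images)

  expect_error(generate_synthetic_objects(2, 2, size = 16, seed = 1),
               "at least 32")
})

test_that("views of one object form pixel-correlation blocks", {
  s <- generate_synthetic_objects(9, 9, size = 256, seed = 7)
  M <- vapply(s$images, as.numeric, numeric(256^2))
  C <- stats::cor(M)
  obj <- rep(1:9, each = 9)
  off <- !diag(81)
  same <- outer(obj, obj, `==`)
  # global block structure
  expect_gt(mean(C[same & off]), mean(C[!same]))
  # every object's views correlate more with each other (block mean) than
  # with any other object's views
  for (o in 1:9) {
    within_o <- mean(C[obj == o, obj == o][off[obj == o, obj == o]])
    cross_o <- max(vapply(setdiff(1:9, o), function(j)
      mean(C[obj == o, obj == j]), 1))
    expect_gt(within_o, cross_o)
  }
})

test_that("stimulus sets round-trip through a PNG directory", {
  s <- generate_synthetic_objects(3, 2, size = 64, seed = 4)
  dir <- withr::local_tempdir()
  write_stimulus_set(s, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  r <- load_image_directory(dir, size = 64)
  expect_s3_class(r, "stimulus_set")
  expect_equal(r$n_objects, 3)
  expect_equal(r$n_views, 2)
  # PNG quantises to 1/255; tolerance matches
  for (i in seq_along(s$images))
    expect_equal(r$images[[i]], s$images[[i]], tolerance = 1 / 200)

  # flat layout (no manifest)
  file.remove(file.path(dir, "manifest.csv"))
  r2 <- load_image_directory(dir, size = 64)
  expect_equal(r2$n_objects, 3)
  expect_identical(r2$images, r$images)
})

test_that("loader converts RGB to luminance and preserves range on resize", {
  dir <- withr::local_tempdir()
  set.seed(1)
  rgb <- array(runif(64 * 64 * 3), c(64, 64, 3))
  png::writePNG(rgb, file.path(dir, "obj0_view0.png"))
  png::writePNG(rgb, file.path(dir, "obj0_view1.png"))
  r <- load_image_directory(dir, size = 64)
  lum <- 0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]
  # RGB input is identical to its luminance conversion (PNG quantisation)
  expect_equal(r$images[[1]], lum, tolerance = 1 / 200)

  # a smaller source resized up still lands in [0, 1]
  png::writePNG(rgb[1:32, 1:32, ], file.path(dir, "obj1_view0.png"))
  png::writePNG(rgb[1:32, 1:32, ], file.path(dir, "obj1_view1.png"))
  r2 <- load_image_directory(dir, size = 64)
  expect_true(all(vapply(r2$images, function(im)
    all(im >= 0 & im <= 1), TRUE)))
})

test_that("unequal view counts are rejected naming the offending object", {
  dir <- withr::local_tempdir()
  img <- matrix(0.5, 16, 16)
  png::writePNG(img, file.path(dir, "obj0_view0.png"))
  png::writePNG(img, file.path(dir, "obj0_view1.png"))
  png::writePNG(img, file.path(dir, "obj1_view0.png"))
  expect_error(load_image_directory(dir, size = 32), "object")
})

test_that("plain PGM images are read in both ascii and binary form", {
  dir <- withr::local_tempdir()
  p2 <- file.path(dir, "a.pgm")
  writeLines(c("P2", "3 2 255", "0 128 255", "64 32 16"), p2)
  g <- visnetr:::read_pgm(p2)
  expect_equal(dim(g), c(2, 3))
  expect_equal(g[1, ], c(0, 128, 255) / 255)

  p5 <- file.path(dir, "b.pgm")
  con <- file(p5, "wb")
  writeChar("P5\n3 2\n255\n", con, eos = NULL)
  writeBin(as.raw(c(0, 128, 255, 64, 32, 16)), con)
  close(con)
  g5 <- visnetr:::read_pgm(p5)
  expect_equal(g5, g)
})
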