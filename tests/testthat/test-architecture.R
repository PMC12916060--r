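test_that("the small-32 preset matches the standard architecture table", {
  specs <- visnet_preset("small-32")
  expect_equal(vapply(specs, function(s) s$dims, 1L), rep(32L, 4))
  expect_equal(vapply(specs, function(s) s$n_connections, 1L),
               c(340L, 200L, 200L, 200L))
  expect_equal(vapply(specs, function(s) s$radius, 1), c(15, 7, 7, 7))
  expect_equal(attr(specs, "input_size"), 256L)
  expect_equal(attr(specs, "input_channels"), 32L)
  # weight ceiling on Layers 1-3, Layer 4 unclipped
  expect_equal(vapply(specs[1:3], function(s) s$max_weight, 1),
               rep(0.06, 3))
  expect_null(specs[[4]]$max_weight)
})

test_that("boundary handling wraps or flags out-of-grid positions", {
  expect_equal(wrap_or_clip_boundaries(33L, 32, "wrap"), 1L)
  expect_equal(wrap_or_clip_boundaries(0L, 32, "wrap"), 32L)
  expect_equal(wrap_or_clip_boundaries(17L, 32, "wrap"), 17L)
  expect_equal(wrap_or_clip_boundaries(17L, 32, "resample"), 17L)
  expect_true(is.na(wrap_or_clip_boundaries(33L, 32, "resample")))
})

test_that("built networks are deterministic with unit-norm initial weights", {
  n1 <- build_network(tiny_specs(), input_size = 64, seed = 5)
  n2 <- build_network(tiny_specs(), input_size = 64, seed = 5)
  expect_identical(n1$layers[[2]]$conn, n2$layers[[2]]$conn)
  expect_identical(n1$layers[[1]]$weights, n2$layers[[1]]$weights)
  n3 <- build_network(tiny_specs(), input_size = 64, seed = 6)
  expect_false(identical(n1$layers[[2]]$conn, n3$layers[[2]]$conn))

  for (l in 1:4) {
    w <- n1$layers[[l]]$weights
    expect_true(all(w >= 0))
    expect_equal(sqrt(rowSums(w^2)), rep(1, nrow(w)), tolerance = 1e-9)
    # one synapse per (pre, post) pair
    expect_true(all(apply(n1$layers[[l]]$conn, 1,
                          function(r) !anyDuplicated(r))))
  }
})

test_that("about 67% of a neuron's connections fall within its radius", {
  net <- fixture("small32_net", function()
    build_network(visnet_preset("small-32"), seed = 21))
  # interior neurons of Layer 2 (radius 7, 200 connections)
  d <- connection_distances(net, 2)
  g <- 32
  x <- rep(seq_len(g), each = g); y <- rep(seq_len(g), times = g)
  interior <- x >= 12 & x <= 21 & y >= 12 & y <= 21
  frac <- rowMeans(d[interior, ] <= 7)
  expect_gte(mean(frac), 0.57)
  expect_lte(mean(frac), 0.77)
  # Layer 1 samples the input volume with radius 15
  d1 <- connection_distances(net, 1)
  frac1 <- rowMeans(d1 <= 15)
  expect_gte(mean(frac1), 0.57)
  expect_lte(mean(frac1), 0.77)
})

test_that("Layer-1 connections favour low spatial frequencies geometrically", {
  net <- fixture("small32_net", function()
    build_network(visnet_preset("small-32"), seed = 21))
  counts <- attr(net$layers[[1]]$conn, "freq_counts")
  expect_equal(sum(counts), 340L)
  expect_true(all(diff(counts) < 0))
  expect_equal(counts, c(181L, 91L, 45L, 23L))  # geometric ratio 1/2 of 340
  # channel indices actually span all four frequency bands
  ch <- (net$layers[[1]]$conn - 1L) %/% (256L * 256L)
  band <- ch %/% 8L
  expect_equal(sort(unique(as.integer(band))), 0:3)
})

test_that("every Layer-4 neuron's transitive input field covers the retina", {
  net <- fixture("small32_net", function()
    build_network(visnet_preset("small-32"), seed = 21))
  # graph reachability down the hierarchy for a handful of Layer-4 neurons,
  # including corners
  for (probe in c(1L, 32L, 1024L - 31L, 1024L, 528L)) {
    reach <- probe
    for (l in 4:2)
      reach <- sort(unique(as.integer(net$layers[[l]]$conn[reach, ])))
    # reach now indexes Layer-1 neurons; collect their retinal footprints
    idx <- net$layers[[1]]$conn[reach, ]
    pos <- (idx - 1L) %% (256L * 256L)
    px <- pos %/% 256L + 1L
    py <- pos %% 256L + 1L
    expect_lt(min(px), 10); expect_gt(max(px), 247)
    expect_lt(min(py), 10); expect_gt(max(py), 247)
  }
})

test_that("infeasible radii are rejected", {
  specs <- list(
    layer_spec(8, 30, 4, sparseness = 0.05),
    layer_spec(8, 64, 0.5, sparseness = 0.05),  # ~4 cells within 4 sigma
    layer_spec(8, 20, 3, sparseness = 0.05),
    layer_spec(8, 20, 3, sparseness = 0.05))
  attr(specs, "input_size") <- 64L
  expect_error(build_network(specs, input_size = 64, seed = 1),
               "too small|exceeds")
})
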