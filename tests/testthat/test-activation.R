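test_that("activations are the inner product of rates and weights", {
  net <- tiny_network()
  # all-zero input -> all-zero activations
  z <- compute_activations(numeric(64), net, 2)
  expect_equal(z, rep(0, 64))
  # dot-product identity on a crafted neuron
  net$layers[[2]]$weights[1, ] <- c(1, rep(0, 19))
  x <- numeric(64)
  x[net$layers[[2]]$conn[1, 1]] <- 0.5
  expect_equal(compute_activations(x, net, 2)[1], 0.5)
  # random instance vs an explicit loop-based oracle
  set.seed(8)
  x <- runif(64)
  r <- compute_activations(x, net, 2)
  oracle <- vapply(seq_len(64), function(i)
    sum(net$layers[[2]]$weights[i, ] * x[net$layers[[2]]$conn[i, ]]), 1)
  expect_equal(r, oracle, tolerance = 1e-12)
  expect_error(compute_activations(numeric(10), net, 2), "length")
})

test_that("sparseness equals the active fraction on binary vectors", {
  for (n in c(10, 100, 1000)) {
    for (k in c(1, n %/% 4, n %/% 2, n)) {
      y <- c(rep(1, k), rep(0, n - k))
      expect_equal(sparseness(y), k / n)
    }
  }
  expect_equal(sparseness(rep(0.3, 50)), 1)
  expect_equal(sparseness(numeric(10)), 0)
  # direct formula evaluation
  y <- c(1, 0.5, 0, 0)
  expect_equal(sparseness(y), ((1.5 / 4)^2) / (1.25 / 4))
  expect_equal(sparseness(y), naive_sparseness(y))
})

test_that("the sigmoid threshold sets the target sparseness", {
  set.seed(10)
  r <- rnorm(1024)
  y <- rates_from_activations(r, a_target = 0.01, beta = 10)
  expect_true(all(y >= 0 & y <= 1))
  # a kept neuron at the threshold fires at exactly 0.5
  th <- attr(y, "threshold")
  at_th <- which(r == th)
  expect_equal(unname(y[at_th]), 0.5)
  # very large beta gives near-binary rates, sparseness ~ kept fraction
  yb <- rates_from_activations(r, a_target = 0.01, beta = 1000)
  kept <- sum(yb > 0)
  expect_equal(sparseness(yb), kept / 1024, tolerance = 0.05)
  expect_true(all(yb[yb > 0] >= 0.5))
  # ~10 of 1024 neurons fire at a = 0.01 (exhaustive-scan cross-check)
  expect_lte(abs(kept - round(0.01 * 1024)), 3)
})

test_that("higher activation never yields a lower rate", {
  set.seed(11)
  for (rep in 1:20) {
    r <- rnorm(200)
    y <- rates_from_activations(r, a_target = runif(1, 0.01, 0.3),
                                beta = runif(1, 1, 100))
    o <- order(r)
    expect_true(all(diff(y[o]) >= -1e-12))
  }
})

test_that("measured sparseness tracks the target within 20%", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(c(256, 500, 1024), 1)
    r <- switch(sample(3, 1), rnorm(n), runif(n), rexp(n))
    a <- sample(c(0.01, 0.02, 0.05, 0.1), 1)
    y <- rates_from_activations(r, a, beta = sample(c(5, 10, 100), 1))
    expect_lt(abs(sparseness(y) - a) / a, 0.2)
  }
})

test_that("identical activations trigger the degenerate top-k path", {
  expect_warning(y <- rates_from_activations(rep(1, 100), 0.05, 10),
                 "identical")
  expect_equal(which(y > 0), 1:5)  # ties broken by index
  expect_equal(unname(y[1]), 0.5)
})

test_that("difference-of-Gaussians inhibition behaves as a zero-sum surround", {
  p <- dog_params(1, 2.5, enabled = TRUE)
  # uniform activation map -> ~0 (interior exactly; border sees padding)
  a <- rep(1, 32^2)
  out <- matrix(lateral_inhibition(a, 32, p), 32, 32)
  expect_lt(max(abs(out[12:20, 12:20])), 1e-12)
  # single active neuron -> positive centre, negative surround ring
  a2 <- numeric(32^2)
  ctr <- (16 - 1) * 32 + 16
  a2[ctr] <- 1
  out2 <- matrix(lateral_inhibition(a2, 32, p), 32, 32)
  expect_gt(out2[16, 16], 0)
  expect_lt(out2[16, 20], 0)
  expect_lt(out2[20, 16], 0)
  # disabled -> identity
  expect_identical(lateral_inhibition(a2, 32, dog_params()), a2)
  # kernel itself is zero-sum
  expect_lt(abs(sum(visnetr:::dog_kernel(1, 2.5))), 1e-12)
})
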