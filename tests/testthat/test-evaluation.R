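test_that("response matrices have the right shape, range and sparseness", {
  net <- tiny_trained()
  fs <- tiny_filtered()
  rm_ <- response_matrix(net, fs)
  expect_equal(dim(rm_), c(9, 64))
  expect_true(all(rm_ >= 0 & rm_ <= 1))
  # per-row sparseness near the layer target
  a <- apply(rm_, 1, sparseness)
  expect_true(all(abs(a - 0.05) / 0.05 < 0.25))
  # identical stimuli give identical rows
  fs2 <- fs
  fs2$data[[2]] <- fs2$data[[1]]
  rm2 <- response_matrix(net, fs2)
  expect_identical(rm2[1, ], rm2[2, ])
  # untrained network warns but still computes
  expect_warning(response_matrix(tiny_network(), fs), "not fully trained")
})

test_that("correlation matrices follow the Pearson conventions", {
  set.seed(20)
  rm_ <- matrix(runif(5 * 40), 5, 40)
  C <- correlation_matrix(rm_)
  expect_equal(diag(C), rep(1, 5))
  expect_equal(C, t(C))
  expect_equal(C[1, 2], stats::cor(rm_[1, ], rm_[2, ]))
  # permuting neuron columns leaves the matrix unchanged
  C2 <- correlation_matrix(rm_[, sample(40)])
  expect_equal(C, C2)
  # zero-variance rows correlate 0 with everything, 1 with themselves
  rm_[3, ] <- 0.7
  C3 <- correlation_matrix(rm_)
  expect_equal(C3[3, 3], 1)
  expect_equal(C3[3, -3], rep(0, 4))
  # one-hot rows: Pearson reduces to the mean-centering term
  oh <- diag(4)
  C4 <- correlation_matrix(oh)
  expect_equal(C4[1, 2], -1 / 3)
})

test_that("object selectivity matches its literal formula and endpoints", {
  # perfect block-diagonal -> 1
  perfect <- kronecker(diag(3), matrix(1, 3, 3))
  expect_equal(object_selectivity(perfect, 3, 3), 1)
  # no correlation anywhere -> 0
  expect_equal(object_selectivity(diag(9), 3, 3), 0)
  # 2 objects x 2 views with within 0.5, between 0.25: literal evaluation
  C <- matrix(0.25, 4, 4)
  C[1:2, 1:2] <- 0.5; C[3:4, 3:4] <- 0.5
  diag(C) <- 1
  # W = 4 * 0.5 = 2; W_perfect = 2*2*1 = 4; B = 8 * 0.25 = 2
  expect_equal(object_selectivity(C, 2, 2), 2 / (4 + 2))
  expect_equal(object_selectivity(C, 2, 2), naive_selectivity(C, 2, 2))
  # negative correlations clip to zero by default
  Cn <- diag(4)
  Cn[1, 2] <- Cn[2, 1] <- -0.5
  expect_equal(object_selectivity(Cn, 2, 2), 0)
  expect_lt(object_selectivity(Cn, 2, 2, clip_negative = FALSE), 0)
  expect_error(object_selectivity(diag(2), 2, 1), "2 views")
})

test_that("selectivity is invariant to relabelling and monotone in between-correlation", {
  set.seed(21)
  rm_ <- matrix(runif(12 * 30), 12, 30)
  C <- correlation_matrix(rm_)
  s0 <- object_selectivity(C, 3, 4)
  # permute objects and views within objects
  perm_obj <- sample(3)
  perm <- as.integer(unlist(lapply(perm_obj, function(o)
    (o - 1) * 4 + sample(4))))
  expect_equal(object_selectivity(C[perm, perm], 3, 4), s0, tolerance = 1e-12)
  # reducing a (positive) between-object correlation strictly increases S
  Ca <- C; Ca[1, 5] <- Ca[5, 1] <- 0.5
  Cb <- C; Cb[1, 5] <- Cb[5, 1] <- 0.25
  expect_gt(object_selectivity(Cb, 3, 4), object_selectivity(Ca, 3, 4))
  expect_equal(naive_selectivity(C, 3, 4), s0)
})

test_that("replicate statistics reproduce hand-computed summaries", {
  # identical seeds give SD = 0; hand check of mean/SD on two runs
  fake <- data.frame(condition = "default", seed = c(1, 1),
                     selectivity = c(0.9, 1.0))
  expect_equal(mean(fake$selectivity), 0.95)
  expect_equal(stats::sd(fake$selectivity), sqrt(0.005))

  cfg <- visnet_config(n_objects = 2, n_views = 2, epochs_per_layer = 1)
  # replicate_statistics on the tiny fixture via a custom filtered set
  rs <- replicate_statistics(cfg, seeds = c(5, 5),
                             filtered = tiny_filtered())
  expect_equal(rs$summary$sd, 0)
  expect_equal(nrow(rs$runs), 2)

  rs2 <- replicate_statistics(
    cfg, seeds = c(3, 4),
    vary = list(comp = list(rule = "competitive_standard"),
                oja = list(rule = "oja")),
    filtered = tiny_filtered())
  expect_equal(nrow(rs2$summary), 2)
  expect_equal(nrow(rs2$t_tests), 1)
  expect_equal(rs2$t_tests$df, 2)  # two-sample equal-variance t
})

test_that("capacity extraction scans the threshold correctly", {
  expect_equal(capacity_from_table(c(10, 20, 40), c(0.9, 0.7, 0.5), 0.6), 20)
  expect_equal(capacity_from_table(c(10), c(0.9), 0.6), 10)
  expect_equal(capacity_from_table(c(10, 20), c(0.5, 0.4), 0.6), 0L)
})

test_that("capacity sweeps reuse leading objects of one master set", {
  cfg <- visnet_config(n_objects = 3, n_views = 3, epochs_per_layer = 1)
  sw <- capacity_sweep(cfg, object_counts = c(2, 3),
                       filtered = tiny_filtered())
  expect_equal(nrow(sw$table), 2)
  expect_equal(sw$table$n_objects, c(2, 3))
  expect_true(all(sw$table$selectivity >= 0 & sw$table$selectivity <= 1))
  sub <- visnetr:::subset_filtered(tiny_filtered(), 1:2)
  expect_equal(sub$n_objects, 2)
  expect_equal(length(sub$data), 6)
})

test_that("weight diagnostics recover lognormal parameters and flag ceilings", {
  set.seed(22)
  net <- tiny_trained()
  # parameter recovery on simulated draws
  fake <- net
  fake$layers[[4]]$weights[] <- stats::rlnorm(length(fake$layers[[4]]$weights),
                                              meanlog = -3, sdlog = 0.5)
  d <- weight_distribution_diagnostics(fake, 4)
  expect_equal(d$lognormal$meanlog, -3, tolerance = 0.05)
  expect_equal(d$lognormal$sdlog, 0.5, tolerance = 0.05)
  # clipped layer: max <= ceiling, near-max fraction reported
  d3 <- weight_distribution_diagnostics(net, 3)
  expect_lte(max(d3$weights), 0.06)
  expect_gte(d3$frac_near_max, 0)
  # zero weights are excluded from the log-domain fit
  fake2 <- net
  w <- fake2$layers[[4]]$weights
  w[seq_len(100)] <- 0
  fake2$layers[[4]]$weights <- w
  d4 <- weight_distribution_diagnostics(fake2, 4)
  expect_equal(d4$n_zero, 100)
  expect_true(is.finite(d4$lognormal$meanlog))
})
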