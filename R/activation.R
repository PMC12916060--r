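#' Neuronal activations of one Layer
#'
#' The activation of each neuron is the inner product between the firing
#' rates of its presynaptic sources and its synaptic weight vector.
#'
#' @param prev_rates numeric vector of presynaptic rates: Layer `l - 1` rates
#'   (length `dims^2`) for `layer_index > 1`, or a flattened filtered input
#'   (from [filtered_input_of()] or `as.numeric` of a `filtered_input`) for
#'   Layer 1.
#' @param network a `visnet_network`.
#' @param layer_index Layer 1--4.
#' @return numeric vector of activations, one per neuron.
#' @export
compute_activations <- function(prev_rates, network, layer_index) {
  ly <- network$layers[[layer_index]]
  expected <- if (layer_index == 1)
    as.numeric(network$input_size)^2 * network$input_channels
  else network$layers[[layer_index - 1]]$spec$dims^2
  if (length(prev_rates) != expected)
    stop("prev_rates has length ", length(prev_rates),
         " but Layer ", layer_index, " expects ", expected)
  layer_activations(ly$weights, ly$conn, as.numeric(prev_rates))
}

# hot path: gather presynaptic rates along the connection lists and take the
# per-neuron weighted sum
layer_activations <- function(W, conn, x) {
  X <- x[conn]
  dim(X) <- dim(W)
  rowSums(W * X)
}

#' Difference-of-Gaussians lateral inhibition
#'
#' Convolves the activation map arranged on the Layer grid with a zero-sum
#' centre-excitatory / surround-inhibitory kernel (zero-padded boundaries).
#' This stage is optional and disabled in the default presets, where the
#' competition is carried entirely by the sparseness-setting threshold.
#'
#' @param activations numeric vector of activations (length `grid^2`,
#'   column-major on the grid).
#' @param grid grid side.
#' @param params list with `sigma_c` (centre), `sigma_s` (surround), and
#'   `enabled`; see [dog_params()].
#' @return filtered activations (identity when disabled).
#' @export
lateral_inhibition <- function(activations, grid, params = dog_params()) {
  if (!isTRUE(params$enabled)) return(activations)
  k <- dog_kernel(params$sigma_c, params$sigma_s)
  a <- matrix(activations, grid, grid)
  hs <- (nrow(k) - 1L) / 2L
  padded <- matrix(0, grid + 2L * hs, grid + 2L * hs)
  padded[hs + seq_len(grid), hs + seq_len(grid)] <- a
  out <- matrix(0, grid, grid)
  for (i in seq_len(nrow(k)))
    for (j in seq_len(ncol(k)))
      out <- out + k[i, j] *
        padded[(i - 1L) + seq_len(grid), (j - 1L) + seq_len(grid)]
  as.numeric(out)
}

#' @rdname lateral_inhibition
#' @param sigma_c,sigma_s centre and surround Gaussian widths (grid units).
#' @param enabled logical.
#' @export
dog_params <- function(sigma_c = 1, sigma_s = 2.5, enabled = FALSE) {
  stopifnot(sigma_s > sigma_c)
  list(sigma_c = sigma_c, sigma_s = sigma_s, enabled = enabled)
}

# exactly zero-sum DoG kernel
dog_kernel <- function(sigma_c, sigma_s) {
  hs <- ceiling(3 * sigma_s)
  d2 <- outer((-hs:hs)^2, (-hs:hs)^2, `+`)
  gc <- exp(-d2 / (2 * sigma_c^2))
  gs <- exp(-d2 / (2 * sigma_s^2))
  gc / sum(gc) - gs / sum(gs)
}

#' Sparseness of a rate vector
#'
#' The population sparseness `a = (sum(y)/n)^2 / (sum(y^2)/n)`. For binary
#' rate vectors this equals the fraction of active neurons; it is 1 when all
#' rates are equal and nonzero, and by convention 0 for an all-zero vector.
#'
#' @param y numeric vector of firing rates.
#' @return sparseness in `[0, 1]`.
#' @export
sparseness <- function(y) {
  stopifnot(length(y) >= 1)
  s2 <- mean(y^2)
  if (s2 == 0) return(0)
  mean(y)^2 / s2
}

#' Convert activations to firing rates at a target sparseness
#'
#' Implements the competition within a Layer: a firing threshold is found by
#' monotone (bisection) search over the sorted activations such that, after
#' zeroing all neurons below the threshold and passing the remainder through
#' the sigmoid `y = 1 / (1 + exp(-2 * beta * (r - threshold)))`, the measured
#' sparseness of the resulting rate vector is as close as possible to
#' `a_target`. Sub-threshold neurons have rate exactly 0; a kept neuron whose
#' activation equals the threshold fires at 0.5. With large `beta` the rates
#' are nearly binary and the measured sparseness approaches the kept
#' fraction. Ties in activation are broken by neuron index.
#'
#' @param activations numeric vector of activations.
#' @param a_target target sparseness in (0, 1].
#' @param beta sigmoid slope (> 0).
#' @return numeric rate vector in `[0, 1]` with attributes `threshold`
#'   (the sigmoid threshold used), `k` (number of neurons kept) and
#'   `sparseness` (measured value).
#' @export
rates_from_activations <- function(activations, a_target, beta) {
  stopifnot(a_target > 0, a_target <= 1, beta > 0)
  n <- length(activations)
  ord <- order(activations, decreasing = TRUE)  # stable: ties by index
  rs <- activations[ord]

  if (rs[1] == rs[n]) {
    warning("all activations identical; degenerate top-k selection by index")
    k <- max(1L, round(a_target * n))
    y <- numeric(n)
    y[sort(ord[seq_len(k)])] <- 0.5
    return(structure(y, threshold = rs[1], k = k, sparseness = sparseness(y)))
  }

  rates_for_k <- function(k) {
    th <- rs[k]
    yk <- 1 / (1 + exp(-2 * beta * (rs[seq_len(k)] - th)))
    a <- (sum(yk) / n)^2 / (sum(yk^2) / n)
    list(a = a, th = th, yk = yk)
  }
  a_of_k <- function(k) rates_for_k(k)$a

  # galloping bracket, then bisection: probes stay near the final k, which
  # is small for sparse targets
  lo <- 1L
  if (a_of_k(1L) >= a_target) {
    hi <- 1L
  } else {
    hi <- 2L
    while (hi < n && a_of_k(hi) < a_target) {
      lo <- hi
      hi <- min(2L * hi, n)
    }
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (a_of_k(mid) < a_target) lo <- mid else hi <- mid
    }
  }
  cand <- unique(c(lo, hi))
  best <- cand[which.min(abs(vapply(cand, a_of_k, 1) - a_target))]
  res <- rates_for_k(best)
  # bisection assumes monotone growth of measured sparseness in k; fall back
  # to an exhaustive threshold scan when the fit is poor
  if (abs(res$a - a_target) / a_target > 0.25 && n <= 8192) {
    as <- vapply(seq_len(n), a_of_k, 1)
    best <- which.min(abs(as - a_target))
    res <- rates_for_k(best)
  }
  y <- numeric(n)
  y[ord[seq_len(best)]] <- res$yk
  structure(y, threshold = res$th, k = best, sparseness = res$a)
}
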