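# Shared fixtures, built lazily and cached for the whole test session.
# Everything is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# -- tiny problem sizes for unit tests ---------------------------------------

# 64 px retina, 8x8 layers: trains in well under a second
tiny_specs <- function(max_weight4 = NULL) {
  specs <- list(
    layer_spec(8, 30, 4, sparseness = 0.05, max_weight = 0.06),
    layer_spec(8, 20, 3, sparseness = 0.05, max_weight = 0.06),
    layer_spec(8, 20, 3, sparseness = 0.05, max_weight = 0.06),
    layer_spec(8, 20, 3, sparseness = 0.05, max_weight = max_weight4))
  attr(specs, "input_size") <- 64L
  attr(specs, "input_channels") <- 32L
  specs
}

tiny_bank <- function() {
  fixture("tiny_bank", function()
    gabor_bank(base_wavelength = 16, size = 64))
}

tiny_set <- function() {
  fixture("tiny_set", function()
    generate_synthetic_objects(3, 3, size = 64, seed = 11))
}

tiny_filtered <- function() {
  fixture("tiny_filtered", function()
    filter_stimulus_set(tiny_set(), tiny_bank()))
}

tiny_network <- function(seed = 3) {
  build_network(tiny_specs(), input_size = 64, seed = seed)
}

tiny_trained <- function() {
  fixture("tiny_trained", function() {
    train_network(tiny_network(), tiny_filtered(),
                  training_schedule(3, seed = 2), learning_config())
  })
}

# -- brute-force oracles ------------------------------------------------------

# direct O(n^2 k^2) 2-D convolution with zero padding (kernel centred)
naive_convolve <- function(img, kernel) {
  hs <- (nrow(kernel) - 1L) / 2L
  n <- nrow(img)
  padded <- matrix(0, n + 2L * hs, n + 2L * hs)
  padded[hs + seq_len(n), hs + seq_len(n)] <- img
  out <- matrix(0, n, n)
  for (di in seq_len(nrow(kernel)))
    for (dj in seq_len(ncol(kernel)))
      out <- out + kernel[di, dj] *
        padded[(di - 1L) + seq_len(n), (dj - 1L) + seq_len(n)]
  out
}

# literal evaluation of the sparseness formula
naive_sparseness <- function(y) {
  n <- length(y)
  (sum(y) / n)^2 / (sum(y^2) / n)
}

# literal object-selectivity sum over an explicit correlation matrix
naive_selectivity <- function(corr, n_objects, n_views) {
  C <- pmax(corr, 0)
  n <- n_objects * n_views
  W <- 0; B <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    oi <- (i - 1) %/% n_views
    oj <- (j - 1) %/% n_views
    if (oi == oj) W <- W + C[i, j] else B <- B + C[i, j]
  }
  W / (n_objects * n_views * (n_views - 1) + B)
}
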