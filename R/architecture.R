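#' Layer specification
#'
#' Parameters of one Layer of the hierarchy: neuron grid side, number of
#' afferent synapses per neuron, connection-sampling radius (in presynaptic
#' grid units; the radius contains about 67% of the Gaussian-sampled
#' connections), target sparseness `a` of the firing-rate representation,
#' sigmoid slope `beta`, and an optional synaptic weight ceiling.
#'
#' @param dims neurons per side of the square grid.
#' @param n_connections afferent synapses per neuron.
#' @param radius connection-sampling radius, presynaptic grid units.
#' @param sparseness target sparseness `a` in (0, 1].
#' @param beta sigmoid slope.
#' @param max_weight weight ceiling, or `NULL` for unclipped.
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(dims, n_connections, radius, sparseness = 0.01,
                       beta = 10, max_weight = NULL) {
  stopifnot(n_connections >= 1, radius > 0,
            sparseness > 0, sparseness <= 1, beta > 0)
  if (!is.null(max_weight)) stopifnot(max_weight > 0)
  structure(list(dims = as.integer(dims),
                 n_connections = as.integer(n_connections),
                 radius = radius, sparseness = sparseness, beta = beta,
                 max_weight = max_weight),
            class = "layer_spec")
}

#' Shipped network presets
#'
#' `"small-32"` is the standard tutorial-scale network: four Layers of
#' 32 x 32 neurons; Layer 1 takes 340 connections from the 256 x 256 x 32
#' filtered input with radius 15 (input-pixel units), Layers 2--4 take 200
#' connections with radius 7 (grid units), and synaptic weights on
#' Layers 1--3 are clipped at 0.06 (the standard MAX_WEIGHT setting for
#' this model family, which keeps weight vectors distributed and prevents a
#' few winner neurons from monopolising every object). `"large-256"` scales
#' the same
#' architecture to 256 x 256 neurons per Layer with up to 1000 synapses per
#' neuron, sparseness 0.0025, beta 100, and a weight ceiling of 0.06 on
#' Layers 1--3 (Layer 2--4 radii scale with the grid).
#'
#' @param name preset name.
#' @param sparseness,beta,max_weight optional overrides applied to all four
#'   Layers (`max_weight` may be a length-4 list / vector; use `NA` or `NULL`
#'   entries for unclipped Layers).
#' @param n_connections optional override of synapses per neuron, applied to
#'   every Layer (used by capacity sweeps).
#' @return list of four [layer_spec()]s, Layer 1 first, plus attributes
#'   `input_size` and `input_channels`.
#' @export
visnet_preset <- function(name = c("small-32", "large-256"),
                          sparseness = NULL, beta = NULL,
                          max_weight = NULL, n_connections = NULL) {
  name <- match.arg(name)
  if (name == "small-32") {
    specs <- list(
      layer_spec(32, 340, 15, max_weight = 0.06),
      layer_spec(32, 200, 7, max_weight = 0.06),
      layer_spec(32, 200, 7, max_weight = 0.06),
      layer_spec(32, 200, 7))
    input_size <- 256L
  } else {
    specs <- list(
      layer_spec(256, 1000, 15, sparseness = 0.0025, beta = 100,
                 max_weight = 0.06),
      layer_spec(256, 1000, 56, sparseness = 0.0025, beta = 100,
                 max_weight = 0.06),
      layer_spec(256, 1000, 56, sparseness = 0.0025, beta = 100,
                 max_weight = 0.06),
      layer_spec(256, 1000, 56, sparseness = 0.0025, beta = 100))
    input_size <- 256L
  }
  for (l in 1:4) {
    if (!is.null(sparseness)) specs[[l]]$sparseness <- sparseness
    if (!is.null(beta)) specs[[l]]$beta <- beta
    if (!is.null(n_connections))
      specs[[l]]$n_connections <- as.integer(n_connections)
  }
  if (!is.null(max_weight)) {
    mw <- if (length(max_weight) == 1) rep(list(max_weight), 4)
          else as.list(max_weight)
    for (l in 1:4) {
      v <- mw[[l]]
      specs[[l]]$max_weight <- if (is.null(v) || is.na(v)) NULL else v
    }
  }
  attr(specs, "input_size") <- input_size
  attr(specs, "input_channels") <- 32L
  specs
}

#' Wrap or keep a sampled presynaptic position
#'
#' Out-of-grid samples are either left to the caller to resample (`"resample"`
#' mode: in-grid positions pass through unchanged, out-of-grid positions are
#' flagged `NA` for redraw) or wrapped toroidally (`"wrap"`).
#'
#' @param position integer vector (or matrix columns x, y) of grid
#'   coordinates, 1-based.
#' @param grid grid side.
#' @param mode `"resample"` or `"wrap"`.
#' @return positions with out-of-grid entries `NA` (resample mode) or wrapped
#'   into `1..grid`.
#' @export
wrap_or_clip_boundaries <- function(position, grid,
                                    mode = c("resample", "wrap")) {
  mode <- match.arg(mode)
  if (mode == "wrap") return(((position - 1L) %% grid) + 1L)
  position[position < 1L | position > grid] <- NA_integer_
  position
}

#' Build a four-Layer network
#'
#' Constructs neuron grids, diluted Gaussian afferent connectivity, and
#' random initial weights. Each neuron samples `n_connections` distinct
#' presynaptic sources from an isotropic 2-D Gaussian centred on its
#' retinotopic projection into the presynaptic sheet, with
#' `sigma = radius / 1.5` so that approximately 67% of connections fall
#' within the stated radius. Layer-1 connections are allocated across the 32
#' input channels with per-frequency counts following a geometric series
#' favouring low spatial frequencies (ratio `freq_ratio`). Duplicate and
#' (in `"resample"` mode) out-of-grid draws are redrawn. Initial weights are
#' uniform positive, normalised to unit Euclidean length per neuron.
#'
#' @param specs list of four [layer_spec()]s (e.g. from [visnet_preset()]).
#' @param input_size retina side in pixels.
#' @param input_channels number of input channels (Gabor bank channels).
#' @param seed integer seed; the build is deterministic per seed.
#' @param edge boundary handling for sampled sources.
#' @param freq_ratio geometric ratio of Layer-1 connection counts from one
#'   frequency band to the next-higher band.
#' @param n_frequencies frequency bands in the input (channels are assumed
#'   frequency-major as produced by [filter_image()]).
#' @return a `visnet_network`.
#' @export
build_network <- function(specs, input_size = 256L, input_channels = 32L,
                          seed = 1L, edge = c("resample", "wrap"),
                          freq_ratio = 0.5, n_frequencies = 4L) {
  edge <- match.arg(edge)
  stopifnot(length(specs) == 4)
  if (!is.null(attr(specs, "input_size")))
    input_size <- attr(specs, "input_size")
  set.seed(as.integer(seed))

  layers <- vector("list", 4)
  for (l in 1:4) {
    sp <- specs[[l]]
    g_post <- sp$dims
    if (l == 1) {
      conn <- sample_layer1_connectivity(sp, input_size, input_channels,
                                         n_frequencies, freq_ratio, edge)
    } else {
      g_pre <- specs[[l - 1]]$dims
      conn <- sample_layer_connectivity(sp, g_pre, edge)
    }
    n_neurons <- g_post^2
    w <- matrix(stats::runif(n_neurons * sp$n_connections),
                n_neurons, sp$n_connections)
    w <- w / sqrt(rowSums(w^2))
    layers[[l]] <- list(spec = sp, conn = conn, weights = w,
                        trained = FALSE, history = NULL)
  }
  structure(list(layers = layers, input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 n_frequencies = as.integer(n_frequencies),
                 seed = as.integer(seed), edge = edge),
            class = "visnet_network")
}

#' @export
print.visnet_network <- function(x, ...) {
  cat("<visnet_network>\n")
  for (l in 4:1) {
    sp <- x$layers[[l]]$spec
    cat(sprintf(
      "  Layer %d: %dx%d neurons, %d connections, radius %g%s%s\n",
      l, sp$dims, sp$dims, sp$n_connections, sp$radius,
      if (!is.null(sp$max_weight))
        sprintf(", max_weight %g", sp$max_weight) else "",
      if (x$layers[[l]]$trained) " [trained]" else ""))
  }
  cat(sprintf("  Input: %dx%dx%d\n", x$input_size, x$input_size,
              x$input_channels))
  invisible(x)
}

# retinotopic projection of postsynaptic grid positions into presynaptic
# continuous coordinates
retinotopic_centres <- function(g_post, pre_extent) {
  pos <- (seq_len(g_post) - 0.5) * pre_extent / g_post + 0.5
  list(x = rep(pos, each = g_post), y = rep(pos, times = g_post))
}

# distinct Gaussian draws on a grid around a centre; returns n linear indices
sample_sources <- function(n, cx, cy, sigma, grid, edge, chan = NULL,
                           chan_pool = NULL, plane = grid^2) {
  picked <- integer(0)
  attempts <- 0L
  while (length(picked) < n) {
    m <- max(2L * (n - length(picked)), 32L)
    x <- round(stats::rnorm(m, cx, sigma))
    y <- round(stats::rnorm(m, cy, sigma))
    if (edge == "wrap") {
      x <- wrap_or_clip_boundaries(x, grid, "wrap")
      y <- wrap_or_clip_boundaries(y, grid, "wrap")
    } else {
      x <- wrap_or_clip_boundaries(x, grid, "resample")
      y <- wrap_or_clip_boundaries(y, grid, "resample")
    }
    x <- as.integer(x); y <- as.integer(y)
    ch <- if (is.null(chan_pool)) chan else sample(chan_pool, m, replace = TRUE)
    idx <- if (is.null(ch)) (x - 1L) * as.integer(grid) + y
           else (ch - 1L) * as.integer(plane) + (x - 1L) * as.integer(grid) + y
    idx <- idx[!is.na(idx)]
    picked <- unique(c(picked, idx))
    attempts <- attempts + 1L
    if (attempts > 200L)
      stop("cannot draw ", n, " distinct sources within the sampling ",
           "radius; radius too small for n_connections")
  }
  picked[seq_len(n)]
}

# Inter-layer connectivity: Gaussian-weighted sampling WITHOUT replacement
# over the presynaptic grid cells. Equivalent to redrawing duplicates from
# the Gaussian, but always feasible (a corner neuron's truncated
# neighbourhood cannot stall it) and vectorised per neuron.
sample_layer_connectivity <- function(sp, g_pre, edge) {
  g_post <- sp$dims
  sigma <- sp$radius / 1.5
  if (sp$n_connections > g_pre^2)
    stop("n_connections (", sp$n_connections, ") exceeds the ", g_pre^2,
         " available presynaptic neurons")
  # reject radii whose ~4 sigma neighbourhood cannot hold the connections
  avail <- sum(outer(seq(-ceiling(4 * sigma), ceiling(4 * sigma)),
                     seq(-ceiling(4 * sigma), ceiling(4 * sigma)),
                     function(a, b) a^2 + b^2) <= (4 * sigma)^2)
  if (min(avail, g_pre^2) < sp$n_connections)
    stop("radius ", sp$radius, " is too small to supply ",
         sp$n_connections, " distinct sources")
  sigma <- calibrate_sigma(sp$radius, sp$n_connections, g_pre)
  ctr <- retinotopic_centres(g_post, g_pre)
  cx <- rep(seq_len(g_pre), each = g_pre)   # cell x for linear index
  cy <- rep(seq_len(g_pre), times = g_pre)  # cell y
  conn <- matrix(0L, g_post^2, sp$n_connections)
  for (i in seq_len(g_post^2)) {
    dx <- abs(cx - ctr$x[i]); dy <- abs(cy - ctr$y[i])
    if (edge == "wrap") {
      dx <- pmin(dx, g_pre - dx); dy <- pmin(dy, g_pre - dy)
    }
    w <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
    conn[i, ] <- sample.int(g_pre^2, sp$n_connections, prob = w)
  }
  conn
}

# For a continuous 2-D Gaussian, the radius holding ~67% of the mass is
# 1.5*sigma. Sampling distinct grid cells depletes the centre and pushes
# connections outward, so the Gaussian scale is calibrated numerically per
# layer to restore the contract that ~67% of the *realised* connections of
# a centrally placed neuron fall within the stated radius.
calibrate_sigma <- function(radius, n_conn, g_pre, target = 0.675,
                            reps = 8L) {
  cx <- rep(seq_len(g_pre), each = g_pre)
  cy <- rep(seq_len(g_pre), times = g_pre)
  c0 <- (g_pre + 1) / 2
  d2 <- (cx - c0)^2 + (cy - c0)^2
  frac_at <- function(sigma) {
    w <- exp(-d2 / (2 * sigma^2))
    mean(vapply(seq_len(reps), function(r) {
      idx <- sample.int(g_pre^2, n_conn, prob = w)
      mean(d2[idx] <= radius^2)
    }, 1))
  }
  hi <- radius / 1.5
  if (frac_at(hi) >= target) return(hi)
  lo <- radius / 6
  for (it in 1:12) {
    mid <- sqrt(lo * hi)
    if (frac_at(mid) >= target) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# Layer 1: sources live in the size x size x channels input volume; counts
# per frequency band follow a geometric series favouring low frequencies
sample_layer1_connectivity <- function(sp, input_size, input_channels,
                                       n_freq, freq_ratio, edge) {
  g_post <- sp$dims
  sigma <- sp$radius / 1.5
  per_band <- input_channels / n_freq
  wts <- freq_ratio^(seq_len(n_freq) - 1)
  counts <- largest_remainder(sp$n_connections * wts / sum(wts))
  ctr <- retinotopic_centres(g_post, input_size)
  conn <- matrix(0L, g_post^2, sp$n_connections)
  plane <- as.numeric(input_size)^2
  for (i in seq_len(g_post^2)) {
    row <- integer(0)
    for (f in seq_len(n_freq)) {
      if (counts[f] == 0L) next
      pool <- (f - 1L) * per_band + seq_len(per_band)
      row <- c(row, sample_sources(counts[f], ctr$x[i], ctr$y[i], sigma,
                                   input_size, edge, chan_pool = pool,
                                   plane = plane))
    }
    conn[i, ] <- row
  }
  attr(conn, "freq_counts") <- counts
  conn
}

# integer apportionment preserving the total
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- as.integer(round(sum(x) - sum(fl)))
  out <- as.integer(fl)
  if (rem > 0) {
    o <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    out[o] <- out[o] + 1L
  }
  out
}

#' Euclidean distance of each connection from its neuron's retinotopic centre
#'
#' Diagnostic used to verify the ~67%-within-radius connectivity contract.
#'
#' @param network a `visnet_network`.
#' @param layer Layer index 1--4.
#' @return matrix (neurons x connections) of distances in presynaptic grid
#'   units.
#' @export
connection_distances <- function(network, layer) {
  ly <- network$layers[[layer]]
  g_post <- ly$spec$dims
  if (layer == 1) {
    g_pre <- network$input_size
    idx <- (ly$conn - 1L) %% (as.numeric(g_pre)^2)  # strip channel block
  } else {
    g_pre <- network$layers[[layer - 1]]$spec$dims
    idx <- ly$conn - 1L
  }
  x <- idx %/% g_pre + 1L
  y <- idx %% g_pre + 1L
  ctr <- retinotopic_centres(g_post, g_pre)
  sqrt((x - ctr$x)^2 + (y - ctr$y)^2)
}
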