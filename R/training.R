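#' Training schedule
#'
#' Presentation plan for layer-by-layer training. Within every epoch all
#' views of one object are presented consecutively in random order before
#' any view of the next object (object-blocked presentation), which is what
#' lets the short-term memory trace associate views of the same object.
#'
#' @param epochs_per_layer number of passes through the stimulus set per
#'   Layer; a single value or one per Layer.
#' @param seed integer seed controlling the view shuffling.
#' @return a `training_schedule`.
#' @export
training_schedule <- function(epochs_per_layer = 50, seed = 1L) {
  stopifnot(all(epochs_per_layer >= 1))
  structure(list(epochs_per_layer = rep(as.integer(epochs_per_layer),
                                        length.out = 4),
                 seed = as.integer(seed)),
            class = "training_schedule")
}

#' Object-blocked presentation order for one epoch
#'
#' @param n_objects,n_views stimulus set dimensions.
#' @param seed epoch-specific seed.
#' @return data.frame with zero-based `object_id`, `view_id` and the
#'   stimulus index `stimulus` into the object-major set, one row per
#'   presentation.
#' @export
presentation_order <- function(n_objects, n_views, seed = 1L) {
  set.seed(as.integer(seed))
  out <- do.call(rbind, lapply(seq_len(n_objects) - 1L, function(o) {
    v <- if (n_views > 1) sample(n_views) - 1L else 0L
    data.frame(object_id = o, view_id = v)
  }))
  out$stimulus <- out$object_id * n_views + out$view_id + 1L
  out
}

epoch_seed <- function(base, layer, epoch) {
  as.integer((as.numeric(base) * 7919 + layer * 104729 + epoch * 31) %%
               .Machine$integer.max)
}

# pre-gather presynaptic values along each neuron's connection list for every
# stimulus: returns a list of (neurons x connections) matrices
pregather_inputs <- function(conn, get_x, n_stimuli) {
  lapply(seq_len(n_stimuli), function(s) {
    x <- get_x(s)
    X <- x[conn]
    dim(X) <- dim(conn)
    X
  })
}

# gather straight from a filtered_set; with byte storage only the gathered
# values are dequantised, not the whole input volume
pregather_filtered <- function(conn, fs) {
  if (fs$storage == "byte") {
    lapply(fs$data, function(raw) {
      X <- as.integer(raw[conn]) / 255
      dim(X) <- dim(conn)
      X
    })
  } else {
    pregather_inputs(conn, function(s) fs$data[[s]], length(fs$data))
  }
}

#' Train one Layer
#'
#' Runs the scheduled epochs for `layer_index`: for every presentation the
#' stimulus is propagated through the (frozen) lower Layers, this Layer's
#' rates are computed with the sparseness-setting sigmoid, the memory trace
#' is updated, and this Layer's weights are updated with the configured rule
#' (with clipping when a weight ceiling is set). Layer 1 learns with the
#' instantaneous rate (no trace); Layers 2--4 learn with the trace. Weights
#' of all other Layers are untouched.
#'
#' @param network a `visnet_network` whose Layers below `layer_index` are
#'   trained (Layer 1 needs no trained predecessors).
#' @param layer_index Layer to train, 1--4.
#' @param filtered a `filtered_set` from [filter_stimulus_set()].
#' @param schedule a [training_schedule()].
#' @param config a [learning_config()].
#' @param verbose print per-epoch mean weight change.
#' @return the network with this Layer trained.
#' @export
train_layer <- function(network, layer_index, filtered, schedule, config,
                        verbose = FALSE) {
  stopifnot(inherits(filtered, "filtered_set"),
            layer_index >= 1, layer_index <= 4)
  if (layer_index > 1) {
    below <- vapply(network$layers[seq_len(layer_index - 1)],
                    function(l) l$trained, TRUE)
    if (!all(below))
      stop("Layers below ", layer_index, " must be trained first")
  }
  X <- pregather_for_layer(network, layer_index, filtered)
  train_layer_impl(network, layer_index, X, filtered$n_objects,
                   filtered$n_views, schedule, config, verbose)
}

# pre-gathered presynaptic input for one layer, propagating through frozen
# lower layers where needed
pregather_for_layer <- function(network, layer_index, filtered) {
  S <- length(filtered$data)
  if (layer_index == 1) {
    pregather_filtered(network$layers[[1]]$conn, filtered)
  } else {
    prev <- propagate_rates(network, filtered, upto = layer_index - 1)
    pregather_inputs(network$layers[[layer_index]]$conn,
                     function(s) prev[s, ], S)
  }
}

# Simulation engine: the compiled kernel is the default; the pure-R
# reference engine implements the same algorithm and is used in parity
# tests (options(visnetr.engine = "r") switches globally).
visnet_engine <- function() {
  match.arg(getOption("visnetr.engine", "cpp"), c("cpp", "r"))
}

# rates of Layer `upto` for every stimulus (no learning, no trace):
# (stimuli x neurons) matrix
propagate_rates <- function(network, filtered, upto,
                            engine = visnet_engine()) {
  S <- length(filtered$data)
  rates <- NULL
  for (l in seq_len(upto)) {
    ly <- network$layers[[l]]
    sp <- ly$spec
    X <- if (l == 1) pregather_filtered(ly$conn, filtered)
         else pregather_inputs(ly$conn, function(s) rates[s, ], S)
    rates <- layer_rates_for_inputs(ly, X, engine)
  }
  rates
}

layer_rates_for_inputs <- function(ly, X, engine = visnet_engine()) {
  sp <- ly$spec
  if (engine == "cpp")
    return(cpp_layer_rates(ly$weights, X, sp$sparseness, sp$beta))
  out <- matrix(0, length(X), sp$dims^2)
  for (s in seq_along(X)) {
    r <- cpp_activations(ly$weights, X[[s]])
    out[s, ] <- rates_from_activations(r, sp$sparseness, sp$beta)
  }
  out
}

train_layer_impl <- function(network, layer_index, X, n_objects, n_views,
                             schedule, config, verbose = FALSE,
                             engine = visnet_engine()) {
  ly <- network$layers[[layer_index]]
  sp <- ly$spec
  W <- ly$weights
  n_neurons <- nrow(W)
  mw <- if (!is.null(config$max_weight)) config$max_weight[[layer_index]]
        else sp$max_weight
  lr <- config$learning_rate
  use_trace <- layer_index > 1
  history <- numeric(0)
  # the ceiling binds from the start of training: initial weights above it
  # on never-active neurons must not outlive a "clipped" run
  if (!is.null(mw) && lr > 0) W <- clip_weights(W, mw)

  if (engine == "cpp") {
    n_epochs <- schedule$epochs_per_layer[layer_index]
    P <- n_objects * n_views
    order_obj <- matrix(0L, n_epochs, P)
    order_stim <- matrix(0L, n_epochs, P)
    for (epoch in seq_len(n_epochs)) {
      ord <- presentation_order(n_objects, n_views,
                                epoch_seed(schedule$seed, layer_index,
                                           epoch))
      order_obj[epoch, ] <- ord$object_id
      order_stim[epoch, ] <- ord$stimulus
    }
    W <- W + 0  # private copy; the kernel updates it in place
    rule_code <- match(config$rule, c("competitive_standard", "oja",
                                      "hebb_normalized")) - 1L
    history <- cpp_train_layer(
      W, X, order_obj, order_stim, sp$sparseness, sp$beta, lr,
      config$eta, rule_code,
      if (is.null(mw)) 0 else mw, !is.null(mw),
      use_trace, config$use_previous_trace_only,
      config$reset_trace_between_objects)
    if (verbose)
      message(sprintf("Layer %d: %d epochs, final mean |dw| = %.3g",
                      layer_index, n_epochs, history[n_epochs]))
    network$layers[[layer_index]]$weights <- W
    network$layers[[layer_index]]$trained <- TRUE
    network$layers[[layer_index]]$history <- history
    return(network)
  }

  for (epoch in seq_len(schedule$epochs_per_layer[layer_index])) {
    ord <- presentation_order(n_objects, n_views,
                              epoch_seed(schedule$seed, layer_index, epoch))
    trace <- numeric(n_neurons)
    last_obj <- -1L
    change <- 0
    for (p in seq_len(nrow(ord))) {
      obj <- ord$object_id[p]
      s <- ord$stimulus[p]
      if (use_trace && config$reset_trace_between_objects &&
          obj != last_obj)
        trace[] <- 0
      xg <- X[[s]]
      r <- cpp_activations(W, xg)
      y <- rates_from_activations(r, sp$sparseness, sp$beta)
      post <- if (!use_trace) as.numeric(y)
              else if (config$use_previous_trace_only) trace
              else update_trace(y, trace, config$eta)
      active <- if (lr == 0) integer(0) else which(post > 0)
      if (length(active)) {
        old <- W[active, , drop = FALSE]
        upd <- apply_rule(config$rule, old,
                          xg[active, , drop = FALSE],
                          post[active], lr)
        upd <- clip_weights(upd, mw)
        W[active, ] <- upd
        change <- change + sum(abs(upd - old))
      }
      if (use_trace) trace <- update_trace(y, trace, config$eta)
      last_obj <- obj
    }
    mean_change <- change / length(W)
    history <- c(history, mean_change)
    if (verbose)
      message(sprintf("Layer %d epoch %d: mean |dw| = %.3g",
                      layer_index, epoch, mean_change))
  }
  network$layers[[layer_index]]$weights <- W
  network$layers[[layer_index]]$trained <- TRUE
  network$layers[[layer_index]]$history <- history
  network
}

#' Train all four Layers sequentially
#'
#' Layers are trained strictly in order 1 to 4, each to its scheduled epoch
#' count before the next begins: Layer 1 binds Gabor features into local
#' feature combinations with purely associative (trace-free) learning, then
#' Layers 2--4 learn transform invariance with the memory trace. Between
#' Layers, the rates of the freshly trained Layer for every stimulus are
#' computed once and cached (inputs are static across epochs).
#'
#' @inheritParams train_layer
#' @param return_rates if `TRUE`, also return the Layer-4 test response
#'   matrix (computed from the cached lower-Layer rates, saving a full
#'   forward pass).
#' @return the fully trained network, or (with `return_rates = TRUE`) a
#'   list with `network` and `rate_matrix`.
#' @export
train_network <- function(network, filtered, schedule, config,
                          verbose = FALSE, return_rates = FALSE) {
  stopifnot(inherits(filtered, "filtered_set"),
            length(filtered$data) >= 1)
  S <- length(filtered$data)
  prev_rates <- NULL
  for (l in 1:4) {
    conn <- network$layers[[l]]$conn
    X <- if (l == 1) pregather_filtered(conn, filtered)
    else pregather_inputs(conn, function(s) prev_rates[s, ], S)
    network <- train_layer_impl(network, l, X, filtered$n_objects,
                                filtered$n_views, schedule, config, verbose)
    if (l < 4 || return_rates)
      prev_rates <- layer_rates_for_inputs(network$layers[[l]], X)
  }
  if (return_rates) list(network = network, rate_matrix = prev_rates)
  else network
}
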