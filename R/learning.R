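#' Short-term memory trace update
#'
#' Updates the trace of postsynaptic activity,
#' `trace_new = (1 - eta) * y + eta * trace_old`, elementwise. With
#' `eta = 0` the trace reduces to the instantaneous rate; with rates held at
#' zero the trace decays geometrically as `eta^t`. The trace is what lets
#' temporally adjacent views of one object drive the same synapses.
#'
#' @param y current firing rates in `[0, 1]`.
#' @param trace previous trace values.
#' @param eta trace proportion in `[0, 1)`.
#' @return updated trace vector.
#' @export
update_trace <- function(y, trace, eta) {
  stopifnot(eta >= 0, eta < 1, length(y) == length(trace))
  (1 - eta) * y + eta * trace
}

#' Hebbian update with explicit weight-vector normalisation
#'
#' `w' = w + learning_rate * y_post * x`, followed by rescaling of each
#' neuron's weight vector to unit Euclidean length (the classical competitive
#' network normalisation that keeps all neurons competing on an equal
#' footing).
#'
#' @param w weight vector, or matrix with one neuron per row.
#' @param x presynaptic rates (vector matching `ncol(w)`, or matrix like
#'   `w`).
#' @param y_post postsynaptic term: the memory trace for trace-trained
#'   Layers, or the instantaneous rate for Layer 1. Scalar, or one value per
#'   row of `w`.
#' @param learning_rate learning rate (>= 0; 0 disables learning).
#' @return updated weights, each neuron's vector of unit length.
#' @export
hebb_update_normalized <- function(w, x, y_post, learning_rate = 0.1) {
  if (is.matrix(w)) {
    w2 <- w + learning_rate * y_post * x
    w2 / sqrt(rowSums(w2^2))
  } else {
    w2 <- w + learning_rate * y_post * x
    w2 / sqrt(sum(w2^2))
  }
}

#' Standard competitive network update (weight-dependent heterosynaptic LTD)
#'
#' `w' = w + learning_rate * y_post * (x - w)`. Synapses with presynaptic
#' rate below their current weight on an active postsynaptic neuron are
#' depressed in proportion to their strength, which removes the need for any
#' explicit weight normalisation: with `learning_rate * y_post <= 1` and
#' inputs in `[0, 1]`, weights stay in `[0, 1]` forever (each update is a
#' convex combination of `w` and `x`).
#'
#' @inheritParams hebb_update_normalized
#' @return updated weights (no normalisation applied).
#' @export
competitive_standard_update <- function(w, x, y_post, learning_rate = 0.1) {
  w + learning_rate * y_post * (x - w)
}

#' Oja update
#'
#' `w' = w + learning_rate * y_post * (x - y_post * w)`, which implicitly
#' normalises the weight-vector length. When all postsynaptic rates equal 1
#' (binary rates at maximum), this is identical to
#' [competitive_standard_update()].
#'
#' @inheritParams hebb_update_normalized
#' @return updated weights.
#' @export
oja_update <- function(w, x, y_post, learning_rate = 0.1) {
  w + learning_rate * y_post * (x - y_post * w)
}

#' Clip synaptic weights at a ceiling
#'
#' Elementwise `min(w, max_weight)`; applied after every update when a
#' Layer's `max_weight` is set. Clipping promotes distributed weight vectors
#' by stopping a few synapses from dominating a neuron's response.
#'
#' @param w weights (vector or matrix).
#' @param max_weight positive ceiling, or `NULL` for the identity.
#' @return clipped weights.
#' @export
clip_weights <- function(w, max_weight = NULL) {
  if (is.null(max_weight)) return(w)
  stopifnot(max_weight > 0)
  pmin(w, max_weight)
}

#' Learning configuration
#'
#' Bundles the rule selector and its parameters. The postsynaptic term for
#' Layers 2--4 defaults to the trace from the previous timestep only
#' (`use_previous_trace_only = TRUE`), i.e. learning for the current view is
#' driven purely by recently seen views of the same object; setting it
#' `FALSE` uses the blended trace that includes the current rate. Layer 1 is
#' always trained with the instantaneous rate (purely associative, no
#' trace). By default the trace is reset at object boundaries so the last
#' views of one object are not associated into the next.
#'
#' @param rule `"competitive_standard"` (default), `"oja"`, or
#'   `"hebb_normalized"`.
#' @param learning_rate learning rate (>= 0; 0 disables learning).
#' @param eta trace proportion in `[0, 1)`.
#' @param max_weight optional weight ceiling: a single value, or a length-4
#'   vector/list per Layer (`NA`/`NULL` entries for unclipped Layers).
#'   Overrides the Layer specs when non-`NULL`.
#' @param use_previous_trace_only logical, see Details.
#' @param reset_trace_between_objects logical, see Details.
#' @return a `learning_config`.
#' @export
learning_config <- function(rule = c("competitive_standard", "oja",
                                     "hebb_normalized"),
                            learning_rate = 0.1, eta = 0.8,
                            max_weight = NULL,
                            use_previous_trace_only = TRUE,
                            reset_trace_between_objects = TRUE) {
  rule <- match.arg(rule)
  stopifnot(learning_rate >= 0, eta >= 0, eta < 1)
  mw <- NULL
  if (!is.null(max_weight)) {
    mw <- if (length(max_weight) == 1) rep(list(max_weight), 4)
          else as.list(max_weight)
    stopifnot(length(mw) == 4)
    mw <- lapply(mw, function(v) if (is.null(v) || is.na(v)) NULL else v)
  }
  structure(list(rule = rule, learning_rate = learning_rate, eta = eta,
                 max_weight = mw,
                 use_previous_trace_only = use_previous_trace_only,
                 reset_trace_between_objects = reset_trace_between_objects),
            class = "learning_config")
}

# dispatch one weight update on the active rows of a layer's weight matrix
apply_rule <- function(rule, w, x, y_post, learning_rate) {
  switch(rule,
    hebb_normalized = hebb_update_normalized(w, x, y_post, learning_rate),
    competitive_standard = competitive_standard_update(w, x, y_post,
                                                       learning_rate),
    oja = oja_update(w, x, y_post, learning_rate),
    stop("unknown learning rule: ", rule))
}
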