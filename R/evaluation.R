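#' Layer-4 response matrix at test
#'
#' Forward pass (no learning, no trace) for every (object, view), rows in
#' object-major order.
#'
#' @param network a trained `visnet_network`.
#' @param filtered a `filtered_set` of the test stimuli.
#' @return matrix of Layer-4 firing rates, (objects * views) x neurons.
#' @export
response_matrix <- function(network, filtered) {
  stopifnot(inherits(filtered, "filtered_set"))
  if (!all(vapply(network$layers, function(l) l$trained, TRUE)))
    warning("network is not fully trained; computing responses anyway")
  propagate_rates(network, filtered, upto = 4)
}

#' Pairwise Pearson correlations between stimulus response vectors
#'
#' Correlation between every pair of rows of the rate matrix. Rows with zero
#' variance correlate 0 with everything by convention and 1 with themselves.
#'
#' @param rate_matrix (stimuli x neurons) rate matrix, at least 2 rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(rate_matrix) {
  stopifnot(nrow(rate_matrix) >= 2)
  C <- suppressWarnings(stats::cor(t(rate_matrix)))
  C[is.na(C)] <- 0
  diag(C) <- 1
  C
}

#' Object selectivity of a view-by-object correlation matrix
#'
#' The transform-invariance statistic computed from the Layer-4 correlation
#' matrix over all views of all objects:
#' `S = W / (W_perfect + B)`, where `W` is the sum of within-object
#' off-diagonal correlations, `W_perfect` is that sum for a perfect
#' representation (every within-object off-diagonal correlation equal to 1,
#' i.e. `n_objects * n_views * (n_views - 1)` counting both triangles), and
#' `B` is the sum of all between-object correlations. Negative correlations
#' are clipped at 0 before summation (switchable), which pins the minimum at
#' 0; the maximum, for perfect within-object correlation and no
#' between-object correlation, is 1.
#'
#' @param corr correlation matrix of dimension
#'   `(n_objects * n_views) x (n_objects * n_views)`, rows object-major.
#' @param n_objects,n_views set dimensions; `n_views` must be >= 2.
#' @param clip_negative clip negative correlations to 0 before summing.
#' @return scalar selectivity in `[0, 1]`.
#' @export
object_selectivity <- function(corr, n_objects, n_views,
                               clip_negative = TRUE) {
  n <- n_objects * n_views
  stopifnot(nrow(corr) == n, ncol(corr) == n)
  if (n_views < 2)
    stop("object selectivity is undefined for fewer than 2 views per object")
  C <- if (clip_negative) pmax(corr, 0) else corr
  obj <- rep(seq_len(n_objects), each = n_views)
  same <- outer(obj, obj, `==`)
  off <- !diag(n)
  W <- sum(C[same & off])
  B <- sum(C[!same])
  W_perfect <- n_objects * n_views * (n_views - 1)
  W / (W_perfect + B)
}

#' Evaluate a trained network on a stimulus set
#'
#' Convenience wrapper producing the rate matrix, its correlation matrix and
#' the object-selectivity scalar in one object.
#'
#' @inheritParams response_matrix
#' @return an `evaluation_result` with elements `rate_matrix`, `corr`,
#'   `object_selectivity`, `n_objects`, `n_views`.
#' @export
evaluate_network <- function(network, filtered) {
  rm_ <- response_matrix(network, filtered)
  corr <- correlation_matrix(rm_)
  s <- object_selectivity(corr, filtered$n_objects, filtered$n_views)
  structure(list(rate_matrix = rm_, corr = corr, object_selectivity = s,
                 n_objects = filtered$n_objects, n_views = filtered$n_views),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result: %d objects x %d views, object selectivity %.3f>\n",
    x$n_objects, x$n_views, x$object_selectivity))
  invisible(x)
}

#' Replicate statistics over seeded runs
#'
#' Runs the full train-and-evaluate pipeline once per seed (new network
#' wiring per seed, same stimuli and parameters) for each condition and
#' reports per-condition mean and SD of the object selectivity plus
#' pairwise two-sample equal-variance t statistics between conditions.
#'
#' @param config a [visnet_config()]; the fields in `vary` are overridden
#'   per condition.
#' @param vary named list: one element per condition, each a named list of
#'   config overrides (e.g. `list(oja = list(rule = "oja"))`). A single
#'   unnamed condition runs the config as is.
#' @param seeds integer vector of network seeds (>= 2 for t statistics).
#' @param filtered optional precomputed `filtered_set` (otherwise built from
#'   the config's stimulus parameters).
#' @return list with `runs` (data.frame: condition, seed, selectivity),
#'   `summary` (condition, mean, sd, n) and `t_tests` (pairwise t, df, p).
#' @export
replicate_statistics <- function(config, seeds,
                                 vary = list(default = list()),
                                 filtered = NULL) {
  stopifnot(length(seeds) >= 1)
  if (is.null(filtered)) filtered <- config_filtered(config)
  runs <- NULL
  for (cond in names(vary)) {
    cfg <- modify_config(config, vary[[cond]])
    for (sd_ in seeds) {
      cfg$network_seed <- as.integer(sd_)
      res <- run_visnet(cfg, filtered = filtered)
      runs <- rbind(runs, data.frame(condition = cond, seed = sd_,
                                     selectivity = res$object_selectivity))
    }
  }
  summary <- do.call(rbind, lapply(split(runs, runs$condition), function(d)
    data.frame(condition = d$condition[1], mean = mean(d$selectivity),
               sd = stats::sd(d$selectivity), n = nrow(d))))
  rownames(summary) <- NULL
  t_tests <- NULL
  conds <- names(vary)
  if (length(conds) > 1 && length(seeds) > 1) {
    for (i in seq_along(conds)) for (j in seq_along(conds)) {
      if (i >= j) next
      a <- runs$selectivity[runs$condition == conds[i]]
      b <- runs$selectivity[runs$condition == conds[j]]
      tt <- stats::t.test(a, b, var.equal = TRUE)
      t_tests <- rbind(t_tests, data.frame(
        condition_a = conds[i], condition_b = conds[j],
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value))
    }
  }
  list(runs = runs, summary = summary, t_tests = t_tests)
}

#' Largest object count meeting a selectivity criterion
#'
#' Trains and evaluates the configured network at each object count
#' (ascending), reusing the leading objects of one master stimulus set, and
#' reports the largest count whose selectivity exceeds the criterion along
#' with the full selectivity-versus-count table.
#'
#' @param config a [visnet_config()]; its `n_objects` is overridden by each
#'   count.
#' @param object_counts ascending object counts to test.
#' @param criterion selectivity threshold (objects "stored" must exceed it).
#' @param filtered optional master `filtered_set` covering
#'   `max(object_counts)` objects.
#' @return list with `table` (data.frame: n_objects, selectivity, stored)
#'   and `capacity` (largest passing count; 0 if none pass).
#' @export
capacity_sweep <- function(config, object_counts, criterion = 0.6,
                           filtered = NULL) {
  stopifnot(!is.unsorted(object_counts))
  if (is.null(filtered)) {
    cfg_full <- modify_config(config,
                              list(n_objects = max(object_counts)))
    filtered <- config_filtered(cfg_full)
  }
  tab <- NULL
  for (k in object_counts) {
    cfg <- modify_config(config, list(n_objects = k))
    sub <- subset_filtered(filtered, seq_len(k))
    res <- run_visnet(cfg, filtered = sub)
    tab <- rbind(tab, data.frame(n_objects = k,
                                 selectivity = res$object_selectivity))
  }
  tab$stored <- tab$selectivity > criterion
  list(table = tab, capacity = capacity_from_table(tab$n_objects,
                                                   tab$selectivity,
                                                   criterion))
}

#' @rdname capacity_sweep
#' @param counts,selectivities parallel vectors of object counts and
#'   measured selectivities.
#' @export
capacity_from_table <- function(counts, selectivities, criterion = 0.6) {
  pass <- counts[selectivities > criterion]
  if (!length(pass)) 0L else max(pass)
}

# first k objects of a filtered set
subset_filtered <- function(fs, objects) {
  keep <- fs$labels$object_id %in% (objects - 1L)
  structure(list(data = fs$data[keep], storage = fs$storage,
                 labels = fs$labels[keep, , drop = FALSE],
                 n_objects = length(objects), n_views = fs$n_views,
                 size = fs$size, n_channels = fs$n_channels),
            class = "filtered_set")
}

#' Synaptic weight distribution diagnostics
#'
#' Summarises a trained Layer's weights: histogram, fraction of weights
#' within 10% of the ceiling (the observed maximum when no ceiling is set),
#' and a lognormal fit to the strictly positive weights with a
#' Kolmogorov-Smirnov goodness-of-fit statistic. Cortical synaptic weight
#' distributions are reported to be approximately lognormal, and trained
#' Layers of this model reproduce that shape.
#'
#' @param network a trained `visnet_network`.
#' @param layer Layer index.
#' @param near_max_frac how close (relative) to the ceiling counts as
#'   "near max".
#' @return list with `weights`, `histogram`, `max_weight`, `frac_near_max`,
#'   `n_zero`, and `lognormal` (`meanlog`, `sdlog`, `ks_statistic`), or a
#'   degenerate report when all weights are zero.
#' @export
weight_distribution_diagnostics <- function(network, layer,
                                            near_max_frac = 0.1) {
  w <- as.numeric(network$layers[[layer]]$weights)
  mw <- network$layers[[layer]]$spec$max_weight
  if (all(w == 0))
    return(list(weights = w, degenerate = TRUE, frac_near_max = 0,
                n_zero = length(w), lognormal = NULL))
  ceiling_ <- if (!is.null(mw)) mw else max(w)
  wpos <- w[w > 0]
  fit <- fitdistrplus::fitdist(wpos, "lnorm")
  ks <- suppressWarnings(stats::ks.test(
    wpos, "plnorm",
    meanlog = fit$estimate[["meanlog"]],
    sdlog = fit$estimate[["sdlog"]]))
  list(weights = w,
       histogram = graphics::hist(w, breaks = 50, plot = FALSE),
       degenerate = FALSE,
       max_weight = ceiling_,
       frac_near_max = mean(w >= (1 - near_max_frac) * ceiling_),
       n_zero = sum(w == 0),
       lognormal = list(meanlog = unname(fit$estimate[["meanlog"]]),
                        sdlog = unname(fit$estimate[["sdlog"]]),
                        ks_statistic = unname(ks$statistic)))
}
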