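#' Reproducible run configuration
#'
#' A run is fully determined by its configuration and seeds: stimulus
#' parameters (or an image directory), Gabor bank, network preset with
#' optional per-Layer overrides, learning rule and its parameters, and the
#' training schedule. Invalid rule or preset names are rejected here, before
#' any computation.
#'
#' @param preset network preset name, see [visnet_preset()].
#' @param n_objects,n_views,view_step,stimulus_seed synthetic stimulus
#'   parameters, see [generate_synthetic_objects()].
#' @param image_dir optional directory of multi-view images used instead of
#'   the synthetic generator, see [load_image_directory()].
#' @param base_wavelength lowest-frequency Gabor wavelength in pixels.
#' @param rule,learning_rate,eta,use_previous_trace_only,reset_trace_between_objects
#'   learning parameters, see [learning_config()].
#' @param sparseness,beta,max_weight,n_connections optional preset
#'   overrides, see [visnet_preset()].
#' @param epochs_per_layer,schedule_seed training schedule, see
#'   [training_schedule()].
#' @param network_seed seed for connectivity and initial weights.
#' @param storage filtered-input cache storage, see [filter_stimulus_set()].
#' @return a `visnet_config`.
#' @export
visnet_config <- function(preset = "small-32",
                          n_objects = 9, n_views = 9, view_step = 40,
                          stimulus_seed = 1L, image_dir = NULL,
                          base_wavelength = 32,
                          rule = "competitive_standard",
                          learning_rate = 0.1, eta = 0.8,
                          sparseness = NULL, beta = NULL,
                          max_weight = NULL, n_connections = NULL,
                          use_previous_trace_only = TRUE,
                          reset_trace_between_objects = TRUE,
                          epochs_per_layer = 50,
                          schedule_seed = 1L, network_seed = 1L,
                          storage = "byte") {
  preset <- match.arg(preset, c("small-32", "large-256"))
  rule <- match.arg(rule,
                    c("competitive_standard", "oja", "hebb_normalized"))
  storage <- match.arg(storage, c("byte", "double"))
  stopifnot(n_objects >= 1, n_views >= 1, learning_rate >= 0,
            eta >= 0, eta < 1, all(epochs_per_layer >= 1))
  structure(list(
    version = 1L, preset = preset,
    n_objects = as.integer(n_objects), n_views = as.integer(n_views),
    view_step = view_step, stimulus_seed = as.integer(stimulus_seed),
    image_dir = image_dir, base_wavelength = base_wavelength,
    rule = rule, learning_rate = learning_rate, eta = eta,
    sparseness = sparseness, beta = beta, max_weight = max_weight,
    n_connections = n_connections,
    use_previous_trace_only = use_previous_trace_only,
    reset_trace_between_objects = reset_trace_between_objects,
    epochs_per_layer = epochs_per_layer,
    schedule_seed = as.integer(schedule_seed),
    network_seed = as.integer(network_seed),
    storage = storage), class = "visnet_config")
}

#' @export
print.visnet_config <- function(x, ...) {
  cat(sprintf(
    "<visnet_config: %s, %d objects x %d views, rule %s, %s epochs/layer>\n",
    x$preset, x$n_objects, x$n_views, x$rule,
    paste(x$epochs_per_layer, collapse = "/")))
  invisible(x)
}

#' Apply named overrides to a configuration
#' @param config a `visnet_config`.
#' @param overrides named list of fields to change (revalidated).
#' @return a new `visnet_config`.
#' @export
modify_config <- function(config, overrides) {
  args <- unclass(config)
  args$version <- NULL
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(visnet_config, args)
}

#' @rdname visnet_config
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname visnet_config
#' @export
read_config <- function(path) {
  args <- yaml::read_yaml(path)
  args$version <- NULL
  if (!is.null(args$max_weight)) args$max_weight <- unlist(args$max_weight)
  do.call(visnet_config, args)
}

config_specs <- function(config) {
  visnet_preset(config$preset, sparseness = config$sparseness,
                beta = config$beta, max_weight = config$max_weight,
                n_connections = config$n_connections)
}

config_input_size <- function(config) {
  attr(config_specs(config), "input_size")
}

#' Stimuli and Gabor-filtered inputs for a configuration
#'
#' Generates (or loads) the stimulus set and pushes it through the Gabor
#' bank. Filtering is the most expensive stage of a run and depends only on
#' the stimulus parameters, so the result can be cached and shared across
#' runs that differ only in network seed or learning rule.
#'
#' @param config a `visnet_config`.
#' @param verbose print filtering progress.
#' @return a `filtered_set`.
#' @export
config_filtered <- function(config, verbose = FALSE) {
  size <- config_input_size(config)
  set <- if (!is.null(config$image_dir))
    load_image_directory(config$image_dir, size = size)
  else
    generate_synthetic_objects(config$n_objects, config$n_views,
                               size = size, seed = config$stimulus_seed,
                               view_step = config$view_step)
  bank <- gabor_bank(base_wavelength = config$base_wavelength, size = size)
  filter_stimulus_set(set, bank, storage = config$storage,
                      verbose = verbose)
}

#' Train and evaluate one configured run
#'
#' Executes the pipeline stimuli -> Gabor filtering -> network build ->
#' layer-by-layer training -> evaluation, entirely in memory.
#'
#' @param config a `visnet_config`.
#' @param filtered optional precomputed `filtered_set` (must match the
#'   config's stimulus dimensions); passing one skips generation/filtering.
#' @param verbose progress messages.
#' @return list with `network` (trained), `evaluation`
#'   (an `evaluation_result`) and `object_selectivity`.
#' @export
run_visnet <- function(config, filtered = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "visnet_config"))
  if (is.null(filtered)) filtered <- config_filtered(config, verbose)
  specs <- config_specs(config)
  network <- build_network(specs, seed = config$network_seed)
  schedule <- training_schedule(config$epochs_per_layer,
                                seed = config$schedule_seed)
  lc <- learning_config(rule = config$rule,
                        learning_rate = config$learning_rate,
                        eta = config$eta,
                        max_weight = config$max_weight,
                        use_previous_trace_only =
                          config$use_previous_trace_only,
                        reset_trace_between_objects =
                          config$reset_trace_between_objects)
  tr <- train_network(network, filtered, schedule, lc,
                      verbose = verbose, return_rates = TRUE)
  corr <- correlation_matrix(tr$rate_matrix)
  s <- object_selectivity(corr, filtered$n_objects, filtered$n_views)
  ev <- structure(list(rate_matrix = tr$rate_matrix, corr = corr,
                       object_selectivity = s,
                       n_objects = filtered$n_objects,
                       n_views = filtered$n_views),
                  class = "evaluation_result")
  list(network = tr$network, evaluation = ev, object_selectivity = s)
}

#' Run an experiment and write its artifacts to a directory
#'
#' Runs [run_visnet()] and writes a reproducible run directory: the
#' configuration copy (`config.yaml`), the trained network archive
#' (`network.rds`), the evaluation summary (`selectivity.json`), the
#' correlation-matrix heatmap (`correlation.png`) and a log. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config a `visnet_config`.
#' @param out_dir output directory (created).
#' @param filtered optional precomputed `filtered_set`.
#' @return the [run_visnet()] result, invisibly, with `out_dir` attached.
#' @export
run_experiment <- function(config, out_dir, filtered = NULL) {
  stopifnot(inherits(config, "visnet_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  logf <- file.path(out_dir, "log.txt")
  logline <- function(...) cat(paste0(format(Sys.time(), "%H:%M:%S "), ...,
                                      "\n"), file = logf, append = TRUE)
  stage("config", write_config(config, file.path(out_dir, "config.yaml")))
  logline("config written")
  if (is.null(filtered))
    filtered <- stage("stimuli+gabor", config_filtered(config))
  logline("stimuli filtered: ", length(filtered$data), " images")
  res <- stage("train+evaluate", run_visnet(config, filtered = filtered))
  logline("trained; object selectivity = ",
          format(res$object_selectivity, digits = 4))
  stage("artifacts", {
    saveRDS(res$network, file.path(out_dir, "network.rds"))
    jsonlite::write_json(
      list(object_selectivity = res$object_selectivity,
           n_objects = filtered$n_objects, n_views = filtered$n_views),
      file.path(out_dir, "selectivity.json"), auto_unbox = TRUE,
      digits = NA)
    p <- plot_correlation_matrix(res$evaluation$corr,
                                 n_views = filtered$n_views)
    ggplot2::ggsave(file.path(out_dir, "correlation.png"), p,
                    width = 6, height = 5, dpi = 120)
  })
  logline("artifacts written")
  attr(res, "out_dir") <- out_dir
  invisible(res)
}

#' Compare learning rules on a shared stimulus set
#'
#' Runs [replicate_statistics()] with one condition per rule on one shared
#' stimulus set and seed list, so conditions differ only in the synaptic
#' update rule.
#'
#' @param config a `visnet_config`.
#' @param rules character vector of at least two rule names.
#' @param seeds network seeds (one run per seed per rule).
#' @param filtered optional precomputed `filtered_set`.
#' @return as [replicate_statistics()].
#' @export
compare_rules <- function(config,
                          rules = c("competitive_standard", "oja",
                                    "hebb_normalized"),
                          seeds = 1:10, filtered = NULL) {
  stopifnot(length(rules) >= 2)
  vary <- stats::setNames(lapply(rules, function(r) list(rule = r)), rules)
  replicate_statistics(config, seeds = seeds, vary = vary,
                       filtered = filtered)
}
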