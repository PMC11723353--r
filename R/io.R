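# On-disk formats: CSV for pulses/predictions/decisions, JSON for mixture
# models, classifier weights and reports, YAML for pipeline configuration.
# Every writer has a reader that round-trips losslessly.

#' Write a pulse set to CSV
#'
#' Columns: `window_id,label,peak_offset,v1..v27` (full double precision).
#'
#' @param pulses a [pulse_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pulses <- function(pulses, path) {
  d <- ncol(pulses$values)
  df <- data.frame(window_id = pulses$window_id, label = pulses$label,
                   peak_offset = pulses$peak_offset,
                   pulses$values, stringsAsFactors = FALSE)
  names(df) <- c("window_id", "label", "peak_offset", paste0("v", seq_len(d)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pulse set written by [write_pulses()]
#' @param path CSV file.
#' @return a [pulse_set()].
#' @export
read_pulses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df))
  pulse_set(as.matrix(df[, vcols, drop = FALSE]), df$window_id, df$label, df$peak_offset)
}

#' Save a fitted mixture model as JSON
#' @param model a `gmm_class_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_gmm <- function(model, path) {
  x <- list(class_label = model$class_label, weights = model$weights,
            means = model$means, covariances = model$covariances,
            normal_component = model$normal_component,
            normalization = model$normalization,
            shape_normalize = isTRUE(model$shape_normalize),
            fit_meta = model$fit_meta[c("seed", "loglik", "iterations", "converged")])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Load a mixture model saved by [save_gmm()]
#' @param path JSON file.
#' @return a `gmm_class_model`.
#' @export
load_gmm <- function(path) {
  x <- jsonlite::fromJSON(path)
  covs <- if (is.list(x$covariances)) lapply(x$covariances, as.matrix)
          else lapply(seq_len(dim(x$covariances)[1]),
                      function(i) as.matrix(x$covariances[i, , ]))
  structure(list(class_label = x$class_label, weights = as.numeric(x$weights),
                 means = as.matrix(x$means),
                 covariances = covs,
                 normal_component = as.integer(x$normal_component),
                 normalization = lapply(x$normalization, as.numeric),
                 shape_normalize = isTRUE(x$shape_normalize),
                 fit_meta = x$fit_meta),
            class = "gmm_class_model")
}

#' Save a trained classifier to a directory
#'
#' Writes `config.json`, `weights.json` (flat values plus dimensions) and
#' `normalization.json`.
#'
#' @param model a trained `classifier_model`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_classifier <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(model$cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  w <- lapply(model$weights, function(x)
    list(dim = if (is.matrix(x)) dim(x) else length(x), values = as.numeric(x)))
  jsonlite::write_json(list(weights = w, trained = model$trained,
                            best_epoch = model$best_epoch,
                            history = model$history),
                       file.path(dir, "weights.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  jsonlite::write_json(model$normalization, file.path(dir, "normalization.json"),
                       digits = NA)
  invisible(dir)
}

#' Load a classifier saved by [save_classifier()]
#' @param dir directory written by [save_classifier()].
#' @return a `classifier_model`.
#' @export
load_classifier <- function(dir) {
  cfgl <- jsonlite::fromJSON(file.path(dir, "config.json"))
  cfg <- do.call(classifier_config, cfgl[setdiff(names(cfgl), character(0))])
  wj <- jsonlite::fromJSON(file.path(dir, "weights.json"))
  model <- build_model(cfg)
  model$weights <- lapply(wj$weights, function(x) {
    if (length(x$dim) == 2L) matrix(x$values, x$dim[1], x$dim[2]) else as.numeric(x$values)
  })
  model$normalization <- lapply(jsonlite::fromJSON(file.path(dir, "normalization.json")),
                                as.numeric)
  model$trained <- isTRUE(wj$trained)
  model$best_epoch <- wj$best_epoch
  model$history <- if (!is.null(wj$history)) as.data.frame(wj$history) else NULL
  model
}

#' Write per-window decisions to CSV
#' @param decisions data.frame from [decide_windows()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_decisions <- function(decisions, path) {
  utils::write.csv(decisions, path, row.names = FALSE)
  invisible(path)
}

#' Read decisions written by [write_decisions()]
#' @param path CSV file.
#' @return data.frame of decisions.
#' @export
read_decisions <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), path,
                   precision = 15L)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Fields are revalidated through the component constructors, so a
#' hand-edited file with an invalid value fails loudly.
#'
#' @param path YAML file written by [write_pipeline_config()] (or authored
#'   by hand with the same structure).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  pipeline_config(synth = do.call(synth_config, x$synth),
                  filter = do.call(filter_config, x$filter),
                  gmm = do.call(gmm_settings, x$gmm),
                  classifier = do.call(classifier_config, x$classifier),
                  tau = x$tau, gmm_enabled = x$gmm_enabled,
                  train_rule = x$train_rule, test_rule = x$test_rule,
                  test_fraction = x$test_fraction, seed = x$seed)
}

#' Save trained pipeline artifacts to a directory
#' @param artifacts result of [run_train()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_artifacts <- function(artifacts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  save_classifier(artifacts$classifier, file.path(dir, "classifier"))
  if (!is.null(artifacts$gmm0)) save_gmm(artifacts$gmm0, file.path(dir, "gmm0.json"))
  if (!is.null(artifacts$gmm1)) save_gmm(artifacts$gmm1, file.path(dir, "gmm1.json"))
  write_pipeline_config(artifacts$config, file.path(dir, "config.yaml"))
  jsonlite::write_json(artifacts$run_manifest, file.path(dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load pipeline artifacts saved by [save_artifacts()]
#' @param dir directory written by [save_artifacts()].
#' @return an artifacts list usable by [run_predict()].
#' @export
load_artifacts <- function(dir) {
  cls <- file.path(dir, "classifier")
  if (!dir.exists(cls))
    stop("load_artifacts(): no trained classifier under ", dir, call. = FALSE)
  g0 <- file.path(dir, "gmm0.json"); g1 <- file.path(dir, "gmm1.json")
  list(classifier = load_classifier(cls),
       gmm0 = if (file.exists(g0)) load_gmm(g0) else NULL,
       gmm1 = if (file.exists(g1)) load_gmm(g1) else NULL,
       config = read_pipeline_config(file.path(dir, "config.yaml")),
       run_manifest = jsonlite::fromJSON(file.path(dir, "run_manifest.json")))
}
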