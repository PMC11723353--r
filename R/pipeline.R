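# End-to-end orchestration: preprocess -> mixture-model label filtering ->
# classifier training, and preprocess -> test filtering -> pulse prediction
# -> window decisions -> evaluation. Fully deterministic under the
# configured seeds.

#' Pipeline configuration
#'
#' Bundles the stage configurations, the vote threshold and the filtering
#' rules. The pipeline `seed` deterministically derives the sub-seeds of the
#' mixture fit, the classifier and the train/test split, so one integer
#' reproduces an entire run; the generator keeps its own seed inside
#' `synth`.
#'
#' @param synth a [synth_config()] (used when the pipeline generates its own
#'   data).
#' @param filter a [filter_config()].
#' @param gmm a [gmm_settings()].
#' @param classifier a [classifier_config()].
#' @param tau window vote threshold, see [decide_window()].
#' @param gmm_enabled if `FALSE`, the label/test filtering stage is bypassed
#'   (the unfiltered baseline with the same backbone network).
#' @param train_rule,test_rule filtering rules, see [filter_training()] and
#'   [filter_test()].
#' @param test_fraction share of windows (per subject and class) held out
#'   for window-level testing in [run_experiment()].
#' @param seed pipeline seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = synth_config(),
                            filter = filter_config(),
                            gmm = gmm_settings(),
                            classifier = classifier_config(),
                            tau = 1 / 3,
                            gmm_enabled = TRUE,
                            train_rule = "own_normal",
                            test_rule = "both_abnormal",
                            test_fraction = 0.3,
                            seed = 1L) {
  seed <- as.integer(seed)
  gmm$seed <- derive_seed(seed, 2L)
  classifier$seed <- derive_seed(seed, 3L)
  if (tau <= 0 || tau > 1) stop_cfg("tau", "must lie in (0, 1]")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_cfg("test_fraction", "must lie strictly in (0, 1)")
  structure(list(synth = synth, filter = filter, gmm = gmm,
                 classifier = classifier, tau = tau,
                 gmm_enabled = isTRUE(gmm_enabled),
                 train_rule = match.arg(train_rule, c("own_normal", "both_abnormal")),
                 test_rule = match.arg(test_rule, c("both_abnormal", "own_normal")),
                 test_fraction = as.numeric(test_fraction),
                 seed = seed),
            class = "pipeline_config")
}

#' Split a dataset's windows into train and test sets
#'
#' Stratified by subject and class, deterministic in the seed.
#'
#' @param manifest a dataset manifest (`window_id`, `subject_id`, `label`).
#' @param test_fraction share of each subject-class cell held out.
#' @param seed integer seed.
#' @return list with character vectors `train_ids` and `test_ids`.
#' @export
split_dataset <- function(manifest, test_fraction, seed) {
  set.seed(derive_seed(seed, 4L))
  test_ids <- character(0)
  for (s in unique(manifest$subject_id)) {
    for (cl in unique(manifest$label)) {
      ids <- manifest$window_id[manifest$subject_id == s & manifest$label == cl]
      if (length(ids) == 0) next
      n_test <- max(1L, floor(length(ids) * test_fraction))
      test_ids <- c(test_ids, sample(ids, n_test))
    }
  }
  list(train_ids = setdiff(manifest$window_id, test_ids),
       test_ids = sort(test_ids))
}

#' Train the full pipeline on labeled windows
#'
#' Preprocesses every training window into single pulses, computes the
#' shared normalization statistics, fits one 2-component mixture per class,
#' selects trainable pulses, and trains the pulse classifier.
#'
#' @param dataset a `ppg_dataset`.
#' @param config a [pipeline_config()].
#' @param window_ids optional subset of window ids to train on.
#' @return artifacts list: `classifier`, `gmm0`, `gmm1` (NULL when filtering
#'   is disabled), `gmm_report`, `config`, `run_manifest` (per-stage counts
#'   and config hash).
#' @export
run_train <- function(dataset, config = pipeline_config(), window_ids = NULL) {
  windows <- dataset$windows
  if (!is.null(window_ids)) windows <- windows[window_ids]
  if (length(windows) == 0) stop("run_train(): no training windows", call. = FALSE)

  prep <- tryCatch(preprocess_dataset(windows, config$filter),
                   error = function(e) stop("run_train() [preprocess]: ",
                                            conditionMessage(e), call. = FALSE))
  pulses <- prep$pulses
  if (anyNA(pulses$label))
    stop("run_train(): training windows must be labeled", call. = FALSE)
  normalization <- compute_normalization(pulses$values)

  gmm0 <- gmm1 <- NULL
  gmm_report <- NULL
  if (config$gmm_enabled) {
    p0 <- pulses[pulses$label == 0L]
    p1 <- pulses[pulses$label == 1L]
    # pooled standardization in the mixture's own fitting space
    gmm_norm <- if (config$gmm$shape_normalize)
      compute_normalization(shape_normalize_values(pulses$values))
    else normalization
    gmm0 <- tryCatch(fit_class_gmm(p0, config$gmm, gmm_norm, class_label = 0L),
                     error = function(e) stop("run_train() [gmm class 0]: ",
                                              conditionMessage(e), call. = FALSE))
    gmm1 <- tryCatch(fit_class_gmm(p1, config$gmm, gmm_norm, class_label = 1L),
                     error = function(e) stop("run_train() [gmm class 1]: ",
                                              conditionMessage(e), call. = FALSE))
    ft <- filter_training(p0, p1, gmm0, gmm1, rule = config$train_rule)
    train_pulses <- bind_pulses(ft$kept0, ft$kept1)
    gmm_report <- ft$report
  } else {
    train_pulses <- pulses
  }

  model <- build_model(config$classifier)
  model <- tryCatch(train_classifier(model, train_pulses,
                                     normalization = normalization),
                    error = function(e) stop("run_train() [classifier]: ",
                                             conditionMessage(e), call. = FALSE))

  run_manifest <- list(
    config_hash = object_hash(rapply(unclass(config), unclass, how = "replace")),
    seed = config$seed,
    counts = list(windows_in = length(windows),
                  pulses_extracted = unname(prep$counts["n_extracted"]),
                  pulses_after_amplitude = unname(prep$counts["n_retained"]),
                  pulses_after_gmm = n_pulses(train_pulses)))
  list(classifier = model, gmm0 = gmm0, gmm1 = gmm1, gmm_report = gmm_report,
       normalization = normalization, config = config, run_manifest = run_manifest)
}

#' Apply a trained pipeline to windows
#'
#' Preprocesses each window, removes indiscernible pulses with the two class
#' mixtures (when filtering is enabled), predicts each surviving pulse with
#' the classifier, and aggregates per window with the vote rule. Windows
#' whose pulses were all removed come out `indeterminate`.
#'
#' @param artifacts result of [run_train()] (or [load_artifacts()]).
#' @param dataset a `ppg_dataset`.
#' @param window_ids optional subset of window ids to predict.
#' @return list: `decisions` (data.frame), `pulse_preds` (data.frame
#'   `window_id,label_pred,prob`), `report` (an `eval_report`, or NULL when
#'   the windows carry no labels), `counts`.
#' @export
run_predict <- function(artifacts, dataset, window_ids = NULL) {
  if (is.null(artifacts$classifier) || !isTRUE(artifacts$classifier$trained))
    stop("run_predict(): artifacts contain no trained classifier", call. = FALSE)
  config <- artifacts$config
  windows <- dataset$windows
  if (!is.null(window_ids)) windows <- windows[window_ids]
  if (length(windows) == 0) stop("run_predict(): no windows to predict", call. = FALSE)

  per <- lapply(windows, preprocess_window, cfg = config$filter, details = TRUE)
  totals <- vapply(per, function(x) unname(x$counts["n_retained"]), numeric(1))
  names(totals) <- vapply(windows, `[[`, "", "window_id")
  pulses <- do.call(bind_pulses, lapply(per, `[[`, "pulses"))

  n_before <- n_pulses(pulses)
  if (config$gmm_enabled) {
    if (is.null(artifacts$gmm0) || is.null(artifacts$gmm1))
      stop("run_predict(): filtering enabled but mixture models missing", call. = FALSE)
    pulses <- filter_test(pulses, artifacts$gmm0, artifacts$gmm1,
                          rule = config$test_rule)$kept
  }

  if (n_pulses(pulses) > 0) {
    pp <- predict_pulse(artifacts$classifier, pulses)
    pulse_preds <- data.frame(window_id = pulses$window_id,
                              label_pred = pp$label, prob = pp$prob,
                              stringsAsFactors = FALSE)
  } else {
    pulse_preds <- data.frame(window_id = character(0), label_pred = integer(0),
                              prob = numeric(0))
  }
  decisions <- decide_windows(pulse_preds, tau = config$tau, totals = totals)

  report <- NULL
  labels <- vapply(windows, function(w)
    if (is.null(w$label) || is.na(w$label)) NA_integer_ else as.integer(w$label),
    integer(1))
  names(labels) <- names(totals)
  if (!anyNA(labels) && any(decisions$decision != "indeterminate"))
    report <- evaluate_decisions(decisions, labels)

  list(decisions = decisions, pulse_preds = pulse_preds, report = report,
       counts = list(windows = length(windows), pulses_preprocessed = n_before,
                     pulses_after_gmm = n_pulses(pulses)))
}

#' Run a paired comparison of two pipeline configurations
#'
#' Splits the dataset once (stratified by subject and class, from config A's
#' seed), trains both pipelines on the same training windows, evaluates both
#' on the same test windows, and compares them with McNemar's test over the
#' intersection of windows both pipelines decided.
#'
#' @param dataset a labeled `ppg_dataset`.
#' @param config_a,config_b two [pipeline_config()]s (e.g. filtering enabled
#'   vs. disabled with the same backbone).
#' @return list: `report_a`, `report_b`, `mcnemar`, `decisions_a`,
#'   `decisions_b`, `split`, `retention` (per-pipeline training pulse
#'   counts), `n_common`.
#' @export
run_experiment <- function(dataset, config_a, config_b) {
  split <- split_dataset(dataset$manifest, config_a$test_fraction, config_a$seed)
  art_a <- run_train(dataset, config_a, split$train_ids)
  art_b <- run_train(dataset, config_b, split$train_ids)
  pred_a <- run_predict(art_a, dataset, split$test_ids)
  pred_b <- run_predict(art_b, dataset, split$test_ids)

  truth <- stats::setNames(dataset$manifest$label, dataset$manifest$window_id)
  da <- pred_a$decisions[pred_a$decisions$decision != "indeterminate", ]
  db <- pred_b$decisions[pred_b$decisions$decision != "indeterminate", ]
  common <- intersect(da$window_id, db$window_id)
  if (length(common) == 0)
    stop("run_experiment(): the two pipelines decided no common windows", call. = FALSE)
  ca <- (da$decision[match(common, da$window_id)] == "threat") == (truth[common] == 1)
  cb <- (db$decision[match(common, db$window_id)] == "threat") == (truth[common] == 1)

  list(report_a = pred_a$report, report_b = pred_b$report,
       mcnemar = mcnemar_test(ca, cb),
       decisions_a = pred_a$decisions, decisions_b = pred_b$decisions,
       split = split,
       retention = list(a = art_a$run_manifest$counts, b = art_b$run_manifest$counts),
       n_common = length(common))
}
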