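# Window-level decisions and evaluation. Pulse predictions within one 12 s
# window are aggregated by a vote rule: "threat" when at least a fraction
# tau (1/3 by default) of surviving pulse predictions are positive. Windows
# whose pulses were all filtered away are explicitly indeterminate.

#' Decide one window from its pulse-level labels
#'
#' @param pulse_labels 0/1 vector of pulse predictions surviving filtering
#'   for this window (possibly empty).
#' @param tau vote threshold in (0, 1]; the comparison is inclusive, so with
#'   `tau = 1/3` one positive among three pulses is already a threat.
#' @param window_id identifier recorded in the output.
#' @param n_total pulse count for the window after preprocessing but before
#'   test filtering (defaults to `length(pulse_labels)`).
#' @return one-row data.frame: `window_id`, `n_pulses_total`,
#'   `n_pulses_kept`, `n_positive`, `positive_fraction`, `decision`
#'   (`"threat"`, `"no_threat"` or `"indeterminate"`).
#' @export
decide_window <- function(pulse_labels, tau = 1 / 3, window_id = "w",
                          n_total = length(pulse_labels)) {
  if (tau <= 0 || tau > 1) stop_cfg("tau", "must lie in (0, 1]")
  k <- length(pulse_labels)
  npos <- sum(pulse_labels == 1)
  frac <- if (k > 0) npos / k else NA_real_
  dec <- if (k == 0) "indeterminate" else if (frac >= tau) "threat" else "no_threat"
  data.frame(window_id = window_id, n_pulses_total = as.integer(n_total),
             n_pulses_kept = as.integer(k), n_positive = as.integer(npos),
             positive_fraction = frac, decision = dec,
             stringsAsFactors = FALSE)
}

#' Decide all windows from a pulse-prediction table
#'
#' @param preds data.frame with columns `window_id` and `label_pred`
#'   (0/1 pulse predictions after any test filtering).
#' @param tau vote threshold, see [decide_window()].
#' @param totals optional named vector of per-window pulse counts before
#'   test filtering; windows present in `totals` but absent from `preds`
#'   (all pulses removed) are emitted as indeterminate.
#' @return data.frame of per-window decisions.
#' @export
decide_windows <- function(preds, tau = 1 / 3, totals = NULL) {
  ids <- unique(preds$window_id)
  if (!is.null(totals)) ids <- union(ids, names(totals))
  rows <- lapply(ids, function(id) {
    lab <- preds$label_pred[preds$window_id == id]
    nt <- if (!is.null(totals) && id %in% names(totals)) totals[[id]] else length(lab)
    decide_window(lab, tau, window_id = id, n_total = nt)
  })
  do.call(rbind, rows)
}

#' Evaluate window decisions against ground truth
#'
#' Standard binary metrics with class 1 (threat) as positive. Indeterminate
#' windows are excluded from the confusion counts and reported separately.
#' Empty precision/recall denominators yield 0 with a degenerate flag rather
#' than NaN.
#'
#' @param decisions data.frame from [decide_windows()].
#' @param truth named 0/1 vector (names are window ids), or a manifest
#'   data.frame with `window_id` and `label` columns.
#' @return an `eval_report` list: confusion counts `tp`, `fp`, `fn`, `tn`,
#'   `accuracy`, `precision`, `recall`, `f1`, `n_indeterminate`,
#'   `degenerate` flags and `n_evaluated`.
#' @export
evaluate_decisions <- function(decisions, truth) {
  if (is.data.frame(truth)) truth <- stats::setNames(truth$label, truth$window_id)
  ev <- decisions[decisions$decision != "indeterminate", , drop = FALSE]
  if (anyNA(match(ev$window_id, names(truth))))
    stop("evaluate_decisions(): missing truth labels for some decided windows", call. = FALSE)
  if (nrow(ev) == 0)
    stop("evaluate_decisions(): no evaluable (non-indeterminate) windows", call. = FALSE)
  y <- as.integer(truth[ev$window_id])
  yhat <- as.integer(ev$decision == "threat")
  tp <- sum(yhat == 1 & y == 1); fp <- sum(yhat == 1 & y == 0)
  fn <- sum(yhat == 0 & y == 1); tn <- sum(yhat == 0 & y == 0)
  degenerate <- character(0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- c(degenerate, "precision"); 0 }
  rec <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- c(degenerate, "recall"); 0 }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else { degenerate <- c(degenerate, "f1"); 0 }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / nrow(ev),
                 precision = prec, recall = rec, f1 = f1,
                 n_evaluated = nrow(ev),
                 n_indeterminate = sum(decisions$decision == "indeterminate"),
                 degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d (+%d indeterminate)\n", x$n_evaluated, x$n_indeterminate))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  cat(sprintf("  confusion: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  if (length(x$degenerate))
    cat("  degenerate:", paste(x$degenerate, collapse = ", "), "\n")
  invisible(x)
}

#' McNemar's test for two paired classifiers
#'
#' Counts discordant pairs over a common item set: `b` items classifier A got
#' right and B wrong, `c` the reverse. By default, with `b + c >= 25`, the
#' continuity-corrected chi-square statistic
#' `max(|b - c| - 1, 0)^2 / (b + c)` on 1 df is used; with fewer discordant
#' pairs the exact two-sided binomial test on `(b, b + c, 1/2)` is used.
#'
#' @param correct_a,correct_b logical vectors: per-item correctness of the
#'   two classifiers over the same items, in the same order.
#' @param method `"auto"` (default switch at 25 discordant pairs),
#'   `"chi2_cc"` or `"exact"`.
#' @return a `mcnemar_result`: `b`, `c`, `statistic`, `p_value`, `method`,
#'   and `undefined = TRUE` with `p_value = NA` when `b + c == 0`.
#' @export
mcnemar_test <- function(correct_a, correct_b, method = c("auto", "chi2_cc", "exact")) {
  method <- match.arg(method)
  if (length(correct_a) != length(correct_b))
    stop("mcnemar_test(): inputs must be paired (equal length)", call. = FALSE)
  b <- sum(correct_a & !correct_b)
  c_ <- sum(!correct_a & correct_b)
  if (b + c_ == 0) {
    return(structure(list(b = b, c = c_, statistic = NA_real_, p_value = NA_real_,
                          method = "undefined", undefined = TRUE),
                     class = "mcnemar_result"))
  }
  if (method == "auto") method <- if (b + c_ < 25L) "exact" else "chi2_cc"
  if (method == "chi2_cc") {
    stat <- max(abs(b - c_) - 1, 0)^2 / (b + c_)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- min(b, c_)
    p <- min(1, 2 * stats::pbinom(min(b, c_), b + c_, 0.5))
  }
  structure(list(b = b, c = c_, statistic = stat, p_value = p,
                 method = method, undefined = FALSE),
            class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("mcnemar_result: undefined (no discordant pairs)\n")
  } else {
    cat(sprintf("mcnemar_result (%s): b = %d, c = %d, statistic = %.4f, p = %.4g\n",
                x$method, x$b, x$c, x$statistic, x$p_value))
  }
  invisible(x)
}
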