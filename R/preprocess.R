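# Preprocessing: raw 12 s windows -> quality-screened 27-sample single pulses.
# Stages: zero-phase Butterworth bandpass (0.5-8 Hz), adaptive-threshold peak
# detection with inter-beat-interval validity screening, peak-centered
# segmentation, and an absolute-amplitude outlier screen (25,000 counts).

#' Preprocessing configuration
#'
#' @param band_low,band_high bandpass cutoff frequencies in Hz. Content below
#'   `band_low` is treated as baseline wander, above `band_high` as
#'   high-frequency noise.
#' @param filter_order Butterworth order (applied forward-backward, so the
#'   effective attenuation is doubled and the phase is zero).
#' @param amp_threshold absolute-amplitude screen in ADC counts: a pulse whose
#'   maximum absolute filtered value exceeds this is discarded as an outlier.
#' @param pre_samples,post_samples samples kept strictly before/after the
#'   systolic peak; `pre_samples + post_samples + 1` must equal `pulse_len`.
#' @param pulse_len single-pulse length in samples (27 at 25 Hz, about 1.1 s).
#' @param rr_tolerance fractional deviation from the median inter-peak
#'   interval beyond which a peak is rejected as false.
#' @param ma_window_s moving-average window (seconds) for the adaptive peak
#'   detection threshold.
#' @param edge_guard_s margin (seconds) at each window edge in which peak
#'   candidates are ignored; zero-phase filtering leaves edge transients
#'   there, and such peaks could not supply a full pulse anyway.
#' @return a validated `filter_config` list.
#' @export
filter_config <- function(band_low = 0.5, band_high = 8, filter_order = 3L,
                          amp_threshold = 25000,
                          pre_samples = 13L, post_samples = 13L, pulse_len = 27L,
                          rr_tolerance = 0.3, ma_window_s = 0.75,
                          edge_guard_s = 0.2) {
  cfg <- list(band_low = check_nonneg(band_low, "band_low"),
              band_high = check_nonneg(band_high, "band_high"),
              filter_order = check_positive_int(filter_order, "filter_order"),
              amp_threshold = check_nonneg(amp_threshold, "amp_threshold"),
              pre_samples = check_positive_int(pre_samples, "pre_samples"),
              post_samples = check_positive_int(post_samples, "post_samples"),
              pulse_len = check_positive_int(pulse_len, "pulse_len"),
              rr_tolerance = check_nonneg(rr_tolerance, "rr_tolerance"),
              ma_window_s = check_nonneg(ma_window_s, "ma_window_s"),
              edge_guard_s = check_nonneg(edge_guard_s, "edge_guard_s"))
  if (cfg$band_low <= 0 || cfg$band_low >= cfg$band_high)
    stop_cfg("band_low", "must satisfy 0 < band_low < band_high")
  if (cfg$amp_threshold <= 0) stop_cfg("amp_threshold", "must be positive")
  if (cfg$pre_samples + cfg$post_samples + 1L != cfg$pulse_len)
    stop_cfg("pulse_len", "must equal pre_samples + post_samples + 1")
  class(cfg) <- "filter_config"
  cfg
}

#' Construct a set of single pulses
#'
#' The pulse container used throughout the pipeline: a numeric matrix with
#' one `pulse_len`-sample pulse per row, plus aligned provenance vectors.
#'
#' @param values numeric matrix, one pulse per row.
#' @param window_id character vector of source window ids.
#' @param label integer labels (0/1) or `NA` when unlabeled.
#' @param peak_offset 1-based index of the systolic peak within each pulse.
#' @return a `pulse_set`.
#' @export
pulse_set <- function(values, window_id, label, peak_offset) {
  values <- as.matrix(values)
  n <- nrow(values)
  stopifnot(length(window_id) %in% c(1L, n), length(peak_offset) %in% c(1L, n))
  structure(list(values = values,
                 window_id = rep_len(as.character(window_id), n),
                 label = rep_len(as.integer(label), n),
                 peak_offset = rep_len(as.integer(peak_offset), n)),
            class = "pulse_set")
}

empty_pulse_set <- function(pulse_len = 27L) {
  pulse_set(matrix(numeric(0), nrow = 0, ncol = pulse_len),
            character(0), integer(0), integer(0))
}

#' @export
`[.pulse_set` <- function(x, i) {
  pulse_set(x$values[i, , drop = FALSE], x$window_id[i], x$label[i], x$peak_offset[i])
}

#' Number of pulses in a pulse set
#' @param x a `pulse_set`.
#' @export
n_pulses <- function(x) nrow(x$values)

#' Concatenate pulse sets
#' @param ... `pulse_set` objects.
#' @export
bind_pulses <- function(...) {
  sets <- Filter(function(s) n_pulses(s) > 0, list(...))
  if (length(sets) == 0) return(empty_pulse_set())
  pulse_set(do.call(rbind, lapply(sets, `[[`, "values")),
            unlist(lapply(sets, `[[`, "window_id")),
            unlist(lapply(sets, `[[`, "label")),
            unlist(lapply(sets, `[[`, "peak_offset")))
}

#' @export
print.pulse_set <- function(x, ...) {
  cat(sprintf("pulse_set: %d pulses x %d samples, %d windows\n",
              n_pulses(x), ncol(x$values), length(unique(x$window_id))))
  invisible(x)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies an order-`filter_order` Butterworth bandpass forward and backward
#' (`signal::filtfilt`), so passband gain is ~1, stopbands are attenuated,
#' and peaks are not shifted in time.
#'
#' @param samples numeric vector of raw samples.
#' @param fs sampling rate in Hz; must exceed `2 * band_high`.
#' @param cfg a [filter_config()].
#' @return filtered vector of the same length.
#' @export
bandpass_filter <- function(samples, fs, cfg = filter_config()) {
  if (fs <= 2 * cfg$band_high)
    stop_cfg("band_high", sprintf("requires fs > 2 * band_high (fs = %g)", fs))
  min_len <- 6L * (2L * cfg$filter_order + 1L)
  if (length(samples) < min_len)
    stop(sprintf("bandpass_filter(): need at least %d samples, got %d",
                 min_len, length(samples)), call. = FALSE)
  bf <- signal::butter(cfg$filter_order,
                       c(cfg$band_low, cfg$band_high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, samples))
}

# Rolling mean with partial windows at the edges (cumsum-based, O(n)).
rolling_mean <- function(x, w) {
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect valid systolic peaks
#'
#' Candidate peaks are the maxima of contiguous regions where the filtered
#' signal rises above an adaptive threshold (a ~0.75 s moving average plus a
#' small fraction of the signal SD). Candidates must be strict local maxima.
#' A validity screen then rejects false peaks: with three or more candidates,
#' a peak whose every adjacent inter-peak interval deviates from the median
#' interval by more than `rr_tolerance` is excluded.
#'
#' @param filtered bandpass-filtered samples.
#' @param fs sampling rate in Hz.
#' @param cfg a [filter_config()].
#' @return sorted integer vector of peak indices (possibly empty).
#' @export
detect_valid_peaks <- function(filtered, fs, cfg = filter_config()) {
  n <- length(filtered)
  if (n < 3L) return(integer(0))
  sdx <- stats::sd(filtered)
  if (!is.finite(sdx) || sdx == 0) return(integer(0)) # flat signal: no peaks
  w <- max(3L, as.integer(round(cfg$ma_window_s * fs)))
  thr <- rolling_mean(filtered, w) + 0.1 * sdx
  above <- filtered > thr
  if (!any(above)) return(integer(0))
  # contiguous above-threshold regions -> one candidate (the argmax) each
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- integer(0)
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(filtered[seg])])
  }
  # strict local maxima only, outside the edge-transient guard band
  guard <- as.integer(round(cfg$edge_guard_s * fs))
  cand <- cand[cand > max(1L, guard) & cand < n - max(0L, guard - 1L)]
  cand <- cand[filtered[cand] > filtered[cand - 1L] & filtered[cand] >= filtered[cand + 1L]]
  if (length(cand) < 3L) return(sort(cand))

  iv <- diff(cand)
  med <- stats::median(iv)
  dev <- abs(iv - med) / med
  bad <- dev > cfg$rr_tolerance
  # a peak is false when every interval it participates in is implausible
  drop <- logical(length(cand))
  drop[1] <- bad[1]
  drop[length(cand)] <- bad[length(iv)]
  if (length(cand) > 2L) {
    mid <- 2:(length(cand) - 1L)
    drop[mid] <- bad[mid - 1L] & bad[mid]
  }
  sort(cand[!drop])
}

#' Segment the filtered signal into peak-centered single pulses
#'
#' Each valid peak yields one pulse of `pulse_len` samples with the peak at
#' position `pre_samples + 1` (13 samples strictly before, 13 strictly after
#' at defaults, about 1.1 s at 25 Hz). Peaks too close to a window edge to
#' supply the full pre/post context are skipped.
#'
#' @param filtered bandpass-filtered samples.
#' @param peaks integer peak indices from [detect_valid_peaks()].
#' @param cfg a [filter_config()].
#' @param window_id,label provenance recorded on each pulse.
#' @return a [pulse_set()].
#' @export
segment_pulses <- function(filtered, peaks, cfg = filter_config(),
                           window_id = "w", label = NA_integer_) {
  n <- length(filtered)
  ok <- peaks - cfg$pre_samples >= 1L & peaks + cfg$post_samples <= n
  peaks <- peaks[ok]
  if (length(peaks) == 0) return(empty_pulse_set(cfg$pulse_len))
  vals <- t(vapply(peaks, function(p)
    filtered[(p - cfg$pre_samples):(p + cfg$post_samples)],
    numeric(cfg$pulse_len)))
  pulse_set(vals, window_id, label, cfg$pre_samples + 1L)
}

#' Amplitude outlier screen
#'
#' Retains exactly the pulses whose maximum absolute value is at or below
#' `amp_threshold` (25,000 counts by default); order is preserved. Motion
#' artifacts surviving peak validation are typically rejected here.
#'
#' @param pulses a [pulse_set()].
#' @param cfg a [filter_config()].
#' @return the retained `pulse_set`.
#' @export
amplitude_filter <- function(pulses, cfg = filter_config()) {
  if (n_pulses(pulses) == 0) return(pulses)
  mx <- apply(abs(pulses$values), 1, max)
  pulses[mx <= cfg$amp_threshold]
}

#' Preprocess one raw window into screened single pulses
#'
#' Composition of the four stages: bandpass filter, valid-peak detection,
#' peak-centered segmentation, amplitude screen. Deterministic: identical
#' windows give identical pulses.
#'
#' @param window a `ppg_window` (from [generate_window()] or
#'   [read_ppg_dataset()]).
#' @param cfg a [filter_config()].
#' @param details if `TRUE`, also return per-stage counts.
#' @return a [pulse_set()]; with `details = TRUE`, a list with `pulses` and
#'   `counts` (`n_peaks`, `n_extracted`, `n_retained`).
#' @export
preprocess_window <- function(window, cfg = filter_config(), details = FALSE) {
  filt <- bandpass_filter(window$samples, window$fs, cfg)
  peaks <- detect_valid_peaks(filt, window$fs, cfg)
  seg <- segment_pulses(filt, peaks, cfg,
                        window_id = window$window_id,
                        label = if (is.null(window$label)) NA_integer_ else window$label)
  kept <- amplitude_filter(seg, cfg)
  if (!details) return(kept)
  list(pulses = kept,
       counts = c(n_peaks = length(peaks), n_extracted = n_pulses(seg),
                  n_retained = n_pulses(kept)))
}

#' Preprocess every window of a dataset
#'
#' @param ds a `ppg_dataset`, or a plain list of `ppg_window` objects.
#' @param cfg a [filter_config()].
#' @return list with `pulses` (one pooled [pulse_set()]) and `counts`
#'   (summed per-stage counts across windows).
#' @export
preprocess_dataset <- function(ds, cfg = filter_config()) {
  windows <- if (inherits(ds, "ppg_dataset")) ds$windows else ds
  out <- lapply(windows, preprocess_window, cfg = cfg, details = TRUE)
  counts <- Reduce(`+`, lapply(out, `[[`, "counts"))
  list(pulses = do.call(bind_pulses, lapply(out, `[[`, "pulses")),
       counts = c(n_windows = length(windows), counts))
}
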