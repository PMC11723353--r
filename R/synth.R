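# Synthetic wrist-PPG generator: the package's reproducible stand-in for
# smartwatch recordings. Emulates two-class beat morphology and heart-rate
# structure, subject-level variation, "non-responder" label noise, baseline
# wander, white noise and motion-artifact spikes on a raw ADC-count scale.

#' Configuration for the synthetic PPG generator
#'
#' Defaults describe a two-condition wrist-PPG acquisition at 25 Hz in 12 s
#' windows: a calm class (label 0) around 70 bpm and an aroused/threat class
#' (label 1) around 95 bpm with a flatter diastolic wave. A fraction
#' `nonresponder_rho` of subjects are "non-responders": their class-1 windows
#' are generated from class-0 physiology but still carry label 1, which is
#' exactly the label noise the mixture-model filter is designed to remove.
#'
#' @param n_subjects number of simulated subjects.
#' @param windows_per_class_per_subject windows generated per class per subject.
#' @param fs sampling rate in Hz.
#' @param window_s window duration in seconds; `fs * window_s` must be integer.
#' @param hr_mean_0,hr_sd_0 class-0 subject heart-rate distribution (bpm).
#' @param hr_mean_1,hr_sd_1 class-1 subject heart-rate distribution (bpm).
#' @param hr_jitter_sd per-window heart-rate jitter around the subject mean (bpm).
#' @param morph_0,morph_1 beat morphology per class: list with `sys_width`
#'   (systolic Gaussian width, s), `dias_ratio` (diastolic-to-systolic
#'   amplitude ratio) and `dias_delay` (diastolic delay after the systolic
#'   peak, s).
#' @param amp_scale systolic pulse amplitude in ADC counts.
#' @param nonresponder_rho probability that a subject is a non-responder.
#' @param wander_amp,wander_hz baseline-wander sinusoid amplitude (counts) and
#'   frequency (Hz; below the 0.5 Hz high-pass edge so filtering removes it).
#' @param beat_amp_sd per-beat multiplicative amplitude jitter (SD of a
#'   factor centered on 1), emulating respiratory-induced beat-to-beat
#'   amplitude variation; does not perturb beat timing.
#' @param beat_var per-beat morphology variability: list with `width_lsd`,
#'   `ratio_sd`, `delay_sd` as in `subject_var` but drawn fresh for every
#'   beat. This gives the two classes genuinely overlapping single-pulse
#'   distributions and makes pulses within one window heterogeneous, as in
#'   real wrist recordings; does not perturb beat timing.
#' @param noise_sd white-noise standard deviation in counts.
#' @param artifact_rate expected motion-spike count per window (Poisson).
#' @param artifact_amp motion-spike amplitude in counts; the default exceeds
#'   the 25,000-count pulse amplitude screen so artifacts are rejected there.
#' @param subject_var inter-individual variability: list with `width_lsd`
#'   (log-SD multiplying each subject's systolic width), `ratio_sd` and
#'   `delay_sd` (additive SD on the diastolic ratio and delay) and `amp_lsd`
#'   (log-SD of the subject's amplitude factor). Wrist-PPG morphology and
#'   amplitude are strongly subject-specific; this is also what makes a
#'   non-responder's contradictorily labeled windows identifiable, the label
#'   ambiguity the mixture filter targets.
#' @param seed root RNG seed; every subject and window derives its own
#'   sub-stream from it, so generation order never matters.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_subjects = 8L,
                         windows_per_class_per_subject = 25L,
                         fs = 25,
                         window_s = 12,
                         hr_mean_0 = 70, hr_sd_0 = 5,
                         hr_mean_1 = 95, hr_sd_1 = 8,
                         hr_jitter_sd = 2,
                         morph_0 = list(sys_width = 0.11, dias_ratio = 0.45, dias_delay = 0.30),
                         morph_1 = list(sys_width = 0.09, dias_ratio = 0.25, dias_delay = 0.24),
                         amp_scale = 20000,
                         nonresponder_rho = 0.3,
                         wander_amp = 2000, wander_hz = 0.25,
                         beat_amp_sd = 0.10,
                         beat_var = list(width_lsd = 0.08, ratio_sd = 0.10,
                                         delay_sd = 0.02),
                         noise_sd = 300,
                         artifact_rate = 0.3,
                         artifact_amp = 30000,
                         subject_var = list(width_lsd = 0.10, ratio_sd = 0.08,
                                            delay_sd = 0.03, amp_lsd = 0.15),
                         seed = 1L) {
  cfg <- list(
    n_subjects = check_positive_int(n_subjects, "n_subjects"),
    windows_per_class_per_subject =
      check_positive_int(windows_per_class_per_subject, "windows_per_class_per_subject"),
    fs = check_nonneg(fs, "fs"),
    window_s = check_nonneg(window_s, "window_s"),
    hr_mean_0 = check_nonneg(hr_mean_0, "hr_mean_0"),
    hr_sd_0 = check_nonneg(hr_sd_0, "hr_sd_0"),
    hr_mean_1 = check_nonneg(hr_mean_1, "hr_mean_1"),
    hr_sd_1 = check_nonneg(hr_sd_1, "hr_sd_1"),
    hr_jitter_sd = check_nonneg(hr_jitter_sd, "hr_jitter_sd"),
    morph_0 = validate_morph(morph_0, "morph_0"),
    morph_1 = validate_morph(morph_1, "morph_1"),
    amp_scale = check_nonneg(amp_scale, "amp_scale"),
    nonresponder_rho = check_prob(nonresponder_rho, "nonresponder_rho"),
    wander_amp = check_nonneg(wander_amp, "wander_amp"),
    wander_hz = check_nonneg(wander_hz, "wander_hz"),
    beat_amp_sd = check_nonneg(beat_amp_sd, "beat_amp_sd"),
    beat_var = validate_beat_var(beat_var),
    noise_sd = check_nonneg(noise_sd, "noise_sd"),
    artifact_rate = check_nonneg(artifact_rate, "artifact_rate"),
    artifact_amp = check_nonneg(artifact_amp, "artifact_amp"),
    subject_var = validate_subject_var(subject_var),
    seed = check_positive_int(seed + 1L, "seed") - 1L
  )
  if (cfg$fs <= 0) stop_cfg("fs", "must be positive")
  if (cfg$window_s <= 0) stop_cfg("window_s", "must be positive")
  n <- cfg$fs * cfg$window_s
  if (abs(n - round(n)) > 1e-9) stop_cfg("fs", "* window_s must be an integer sample count")
  class(cfg) <- "synth_config"
  cfg
}

validate_beat_var <- function(v, name = "beat_var") {
  need <- c("width_lsd", "ratio_sd", "delay_sd")
  if (!is.list(v) || !all(need %in% names(v)))
    stop_cfg(name, "must be a list with width_lsd, ratio_sd, delay_sd")
  for (f in need) check_nonneg(v[[f]], paste0(name, "$", f))
  v[need]
}

validate_subject_var <- function(v, name = "subject_var") {
  need <- c("width_lsd", "ratio_sd", "delay_sd", "amp_lsd")
  if (!is.list(v) || !all(need %in% names(v)))
    stop_cfg(name, "must be a list with width_lsd, ratio_sd, delay_sd, amp_lsd")
  for (f in need) check_nonneg(v[[f]], paste0(name, "$", f))
  v[need]
}

validate_morph <- function(m, name) {
  need <- c("sys_width", "dias_ratio", "dias_delay")
  if (!is.list(m) || !all(need %in% names(m)))
    stop_cfg(name, "must be a list with sys_width, dias_ratio, dias_delay")
  for (f in need) check_nonneg(m[[f]], paste0(name, "$", f))
  m[need]
}

#' Draw per-subject physiological state
#'
#' Draws the subject's class-wise mean heart rates and the non-responder
#' flag from the configured distributions, on a seed derived from the
#' configuration's root seed and the subject index.
#'
#' @param cfg a [synth_config()].
#' @param subject_idx 1-based subject index.
#' @return list with `subject_id`, `hr0`, `hr1` (bpm), per-class morphology
#'   (`morph0`, `morph1` after subject jitter), `amp_factor` and
#'   `is_nonresponder`.
#' @export
draw_subject_state <- function(cfg, subject_idx) {
  set.seed(derive_seed(cfg$seed, 7L, subject_idx))
  hr0 <- max(35, stats::rnorm(1, cfg$hr_mean_0, cfg$hr_sd_0))
  hr1 <- max(35, stats::rnorm(1, cfg$hr_mean_1, cfg$hr_sd_1))
  sv <- cfg$subject_var
  jitter_morph <- function(m, wf, dr, dd) {
    list(sys_width = m$sys_width * wf,
         dias_ratio = max(0, m$dias_ratio + dr),
         dias_delay = max(0.05, m$dias_delay + dd))
  }
  wf <- exp(stats::rnorm(1, 0, sv$width_lsd))
  dr <- stats::rnorm(1, 0, sv$ratio_sd)
  dd <- stats::rnorm(1, 0, sv$delay_sd)
  list(subject_id = sprintf("s%02d", subject_idx),
       hr0 = hr0, hr1 = hr1,
       morph0 = jitter_morph(cfg$morph_0, wf, dr, dd),
       morph1 = jitter_morph(cfg$morph_1, wf, dr, dd),
       amp_factor = exp(stats::rnorm(1, 0, sv$amp_lsd)),
       is_nonresponder = stats::runif(1) < cfg$nonresponder_rho)
}

# Two-bump beat template evaluated at times t for beat centers ctr, with
# optional per-beat amplitude factors (respiratory modulation) and per-beat
# morphology (lists of width/ratio/delay, one value per beat).
beat_train <- function(t, ctr, morph, beat_amps = rep(1, length(ctr)),
                       beat_morph = NULL) {
  y <- numeric(length(t))
  for (i in seq_along(ctr)) {
    c0 <- ctr[i]
    w <- if (is.null(beat_morph)) morph$sys_width else beat_morph$width[i]
    ratio <- if (is.null(beat_morph)) morph$dias_ratio else beat_morph$ratio[i]
    delay <- if (is.null(beat_morph)) morph$dias_delay else beat_morph$delay[i]
    wd <- 1.8 * w
    y <- y + beat_amps[i] * (exp(-(t - c0)^2 / (2 * w^2)) +
      ratio * exp(-(t - c0 - delay)^2 / (2 * wd^2)))
  }
  y
}

#' Generate one synthetic PPG window
#'
#' Builds a 12 s (by default) raw window: a beat train of systolic plus
#' delayed diastolic Gaussian bumps at the subject's heart rate, scaled to
#' ADC counts, with a DC offset, sinusoidal baseline wander, white noise and
#' Poisson-placed motion-artifact bumps. A non-responder subject's class-1
#' window is generated from class-0 physiology but keeps label 1.
#'
#' @param cfg a [synth_config()].
#' @param class_label 0 (calm) or 1 (threat).
#' @param subject_state result of [draw_subject_state()].
#' @param seed integer seed for this window's sub-stream.
#' @param window_id identifier carried through the pipeline.
#' @return a `ppg_window`: list with `samples` (length `fs * window_s`),
#'   `fs`, `label`, `subject_id`, `window_id`, `is_nonresponder`, and the
#'   ground-truth beat centers `beat_times` (seconds) used for testing.
#' @export
generate_window <- function(cfg, class_label, subject_state, seed,
                            window_id = "w001") {
  if (!class_label %in% c(0, 1)) stop_cfg("class_label", "must be 0 or 1")
  set.seed(seed)
  n <- as.integer(round(cfg$fs * cfg$window_s))
  t <- (seq_len(n) - 1) / cfg$fs

  # Non-responders keep label 1 but produce calm-class physiology.
  phys <- if (class_label == 1 && !subject_state$is_nonresponder) 1L else 0L
  hr <- if (phys == 1L) subject_state$hr1 else subject_state$hr0
  hr <- max(35, hr + stats::rnorm(1, 0, cfg$hr_jitter_sd))
  morph <- if (phys == 1L) subject_state$morph1 else subject_state$morph0
  if (is.null(morph)) morph <- if (phys == 1L) cfg$morph_1 else cfg$morph_0
  amp <- cfg$amp_scale * (subject_state$amp_factor %||% 1)

  period <- 60 / hr
  phase <- stats::runif(1, 0, period)
  ctr <- seq(-phase, cfg$window_s + 2 * period, by = period)
  nb <- length(ctr)
  beat_amps <- if (cfg$beat_amp_sd > 0)
    pmax(0.2, 1 + stats::rnorm(nb, 0, cfg$beat_amp_sd))
  else rep(1, nb)
  bv <- cfg$beat_var
  beat_morph <- if (any(unlist(bv) > 0)) {
    list(width = morph$sys_width * exp(stats::rnorm(nb, 0, bv$width_lsd)),
         ratio = pmax(0, morph$dias_ratio + stats::rnorm(nb, 0, bv$ratio_sd)),
         delay = pmax(0.05, morph$dias_delay + stats::rnorm(nb, 0, bv$delay_sd)))
  } else NULL

  x <- amp * beat_train(t, ctr, morph, beat_amps, beat_morph) + amp
  if (cfg$wander_amp > 0) {
    x <- x + cfg$wander_amp * sin(2 * pi * cfg$wander_hz * t + stats::runif(1, 0, 2 * pi))
  }
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  n_art <- if (cfg$artifact_rate > 0) stats::rpois(1, cfg$artifact_rate) else 0L
  if (n_art > 0) {
    # Narrow bumps (sigma 0.06 s) rather than single-sample deltas, so the
    # spike's energy sits inside the 0.5-8 Hz passband and reaches the
    # amplitude screen instead of being filtered away.
    for (ac in stats::runif(n_art, 0, cfg$window_s)) {
      x <- x + cfg$artifact_amp * exp(-(t - ac)^2 / (2 * 0.06^2))
    }
  }
  structure(list(samples = x, fs = cfg$fs, label = as.integer(class_label),
                 subject_id = subject_state$subject_id, window_id = window_id,
                 is_nonresponder = subject_state$is_nonresponder,
                 beat_times = ctr[ctr >= 0 & ctr < cfg$window_s]),
            class = "ppg_window")
}

#' Generate a full labeled synthetic dataset
#'
#' For each subject draws the physiological state (including the
#' non-responder flag) and emits `windows_per_class_per_subject` windows per
#' class. The manifest records ground truth, including the ambiguity flag
#' that real data would not have.
#'
#' @param cfg a [synth_config()].
#' @return a `ppg_dataset`: list with `windows` (named list of `ppg_window`),
#'   `manifest` (data.frame: window_id, subject_id, label, fs, window_s,
#'   is_nonresponder, seed) and `config`.
#' @export
generate_dataset <- function(cfg) {
  windows <- list()
  rows <- vector("list", cfg$n_subjects * 2L * cfg$windows_per_class_per_subject)
  i <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    st <- draw_subject_state(cfg, s)
    for (cl in c(0L, 1L)) {
      for (w in seq_len(cfg$windows_per_class_per_subject)) {
        i <- i + 1L
        wid <- sprintf("%s_c%d_w%03d", st$subject_id, cl, w)
        wseed <- derive_seed(cfg$seed, s, 100L + cl, w)
        windows[[wid]] <- generate_window(cfg, cl, st, wseed, window_id = wid)
        rows[[i]] <- data.frame(window_id = wid, subject_id = st$subject_id,
                                label = cl, fs = cfg$fs, window_s = cfg$window_s,
                                is_nonresponder = st$is_nonresponder,
                                seed = wseed, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(windows = windows, manifest = do.call(rbind, rows), config = cfg),
            class = "ppg_dataset")
}

#' Export a dataset to per-window CSV files plus a JSON manifest
#'
#' Writes one CSV per window (header `sample`, one raw value per row, full
#' double precision) and `manifest.json`. The export round-trips losslessly
#' through [read_ppg_dataset()].
#'
#' @param ds a `ppg_dataset` from [generate_dataset()].
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
export_dataset <- function(ds, path) {
  if (!inherits(ds, "ppg_dataset") || length(ds$windows) == 0)
    stop("export_dataset(): empty or invalid dataset", call. = FALSE)
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("export_dataset(): cannot create ", path, call. = FALSE)
  for (w in ds$windows) {
    f <- file.path(path, paste0(w$window_id, ".csv"))
    writeLines(c("sample", sprintf("%.17g", w$samples)), f)
  }
  jsonlite::write_json(ds$manifest, file.path(path, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(path)
}

#' Read a dataset exported by [export_dataset()]
#'
#' @param path directory containing per-window CSVs and `manifest.json`.
#' @return a `ppg_dataset` (without the generating config or ground-truth
#'   beat times; `is_nonresponder` is retained from the manifest when present).
#' @export
read_ppg_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("read_ppg_dataset(): no manifest.json in ", path, call. = FALSE)
  manifest <- jsonlite::fromJSON(mf)
  windows <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    vals <- as.numeric(readLines(file.path(path, paste0(r$window_id, ".csv")))[-1])
    windows[[r$window_id]] <- structure(
      list(samples = vals, fs = r$fs, label = r$label,
           subject_id = r$subject_id, window_id = r$window_id,
           is_nonresponder = if ("is_nonresponder" %in% names(manifest)) r$is_nonresponder else NA,
           beat_times = NULL),
      class = "ppg_window")
  }
  structure(list(windows = windows, manifest = manifest, config = NULL),
            class = "ppg_dataset")
}

#' @export
print.ppg_dataset <- function(x, ...) {
  cat(sprintf("ppg_dataset: %d windows, %d subjects, fs = %g Hz\n",
              length(x$windows), length(unique(x$manifest$subject_id)),
              x$manifest$fs[1]))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%d x class %s", table(x$manifest$label),
                            names(table(x$manifest$label))), collapse = ", ")))
  invisible(x)
}
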