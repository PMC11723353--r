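# Shared fixtures, all generated in code.

# Noise-free single-subject configuration at a fixed heart rate.
clean_cfg <- function(hr = 60, ...) {
  synth_config(n_subjects = 1, windows_per_class_per_subject = 1,
               hr_mean_0 = hr, hr_sd_0 = 0, hr_jitter_sd = 0,
               noise_sd = 0, wander_amp = 0, artifact_rate = 0,
               beat_amp_sd = 0, nonresponder_rho = 0,
               beat_var = list(width_lsd = 0, ratio_sd = 0, delay_sd = 0),
               subject_var = list(width_lsd = 0, ratio_sd = 0,
                                  delay_sd = 0, amp_lsd = 0),
               ...)
}

clean_window <- function(hr = 60, seed = 42, class_label = 0, ...) {
  cfg <- clean_cfg(hr = hr, ...)
  st <- draw_subject_state(cfg, 1)
  generate_window(cfg, class_label, st, seed)
}

# Small two-cluster pulse fixture in 27 dimensions.
two_cluster_pulses <- function(n1 = 350, n2 = 150, sep = 10, sd = 1, seed = 7,
                               d = 27) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n1 * d, 0, sd), ncol = d),
             matrix(stats::rnorm(n2 * d, sep * sd, sd), ncol = d))
  pulse_set(X, "w", 0L, 14L)
}

# Linearly separable labeled pulses for classifier tests.
separable_pulses <- function(n_per_class = 400, shift = 2, seed = 11) {
  set.seed(seed)
  X0 <- matrix(stats::rnorm(n_per_class * 27), ncol = 27)
  X1 <- matrix(stats::rnorm(n_per_class * 27), ncol = 27) + shift
  pulse_set(rbind(X0, X1), "w",
            c(rep(0L, n_per_class), rep(1L, n_per_class)), 14L)
}
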