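# shared fixtures: small deterministic signals and epoch containers

fix_fs <- 250

# single-channel epochs holding an arbitrary signal on the standard
# (-1, 6) s window
tone_epochs <- function(signal_fn, n_trials = 1, fs = fix_fs,
                        window = c(-1, 6), label = "RESS") {
  t <- seq(window[1], window[2] - 1 / fs, by = 1 / fs)
  arr <- array(0, dim = c(n_trials, 1, length(t)))
  for (k in seq_len(n_trials)) arr[k, 1, ] <- signal_fn(t, k)
  epoched_data(arr, fs, t, label, window = window)
}

# multi-channel raw recording from a channels x samples matrix
make_raw <- function(data, fs = fix_fs, events = NULL) {
  raw_recording(data, fs,
                paste0("CH", seq_len(nrow(data))), events)
}

# an assr_demod object built directly from a complex trial x time matrix
# (bypasses the filter chain; used to unit-test AM/ITPC arithmetic)
demod_from_z <- function(z, fs = fix_fs, t_start = -1) {
  t <- t_start + (seq_len(ncol(z)) - 1) / fs
  structure(list(z = z, t = t, fs = fs,
                 settings = demod_settings(),
                 baseline_window = c(-0.5, -0.25)),
            class = "assr_demod")
}

# default-preset feature table columns required by the GLM design
feature_cols <- c("A_am", "mu_am", "sigma_am", "alpha_am",
                  "A_itpc", "mu_itpc", "sigma_itpc", "alpha_itpc", "power")
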