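# programmatic fixtures shared across the test files

# a pure-sinusoid two-channel recording (same wave on both channels)
sine_recording <- function(freq_hz, amplitude = 1, duration = 3,
                           sample_rate = 1000) {
  t <- seq(0, duration - 1 / sample_rate, by = 1 / sample_rate)
  wave <- amplitude * sin(2 * pi * freq_hz * t)
  tibble::tibble(time_s = t, emg_extensor = wave, emg_flexor = wave)
}

# magnitude response of a digital filter b/a at frequency f (Hz)
digital_mag <- function(filt, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  b <- filt$b
  a <- filt$a
  Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))
}

# analytic acquisition-band gain (high-pass then low-pass Butterworth)
band_gain_at <- function(f, spec = emgavatar::filter_spec(), fs = 1000) {
  hp <- signal::butter(spec$order, spec$hp_hz / (fs / 2), "high")
  lp <- signal::butter(spec$order, spec$lp_hz / (fs / 2), "low")
  digital_mag(hp, f, fs) * digital_mag(lp, f, fs)
}

# steady-state mean of the rectified output, skipping the filter transient
rectified_mean <- function(filtered, skip_s = 0.5) {
  with(filtered[filtered$time_s > skip_s, ], mean(emg_extensor))
}

# a minimal two-comparison catalog for protocol edge cases
tiny_catalog <- function(n_comparisons = 2) {
  comps <- lapply(seq_len(n_comparisons), function(i) {
    emgavatar::avatar_setting(paste0("c", i),
                              emgavatar::nmss_params(omega_nm = 2 + i,
                                                     omega_ms = 2 + i),
                              "test")
  })
  names(comps) <- paste0("c", seq_len(n_comparisons))
  structure(list(standard = emgavatar::standard_setting_of(),
                 comparisons = comps, name = "tiny"),
            class = "settings_catalog")
}

# a ratings table with two repetitions per setting built from per-participant
# mean values (both repetitions equal, so repetition means hit them exactly)
ratings_from_means <- function(means_by_setting) {
  # means_by_setting: named list of numeric vectors (one value/participant)
  n <- length(means_by_setting[[1]])
  rows <- lapply(names(means_by_setting), function(s) {
    tidyr::expand_grid(participant_id = seq_len(n), repetition = 1:2) |>
      dplyr::mutate(setting = s,
                    value = means_by_setting[[s]][participant_id])
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(experiment = "test", soo = value, soa = value, cl = value) |>
    dplyr::select(participant_id, experiment, setting, repetition,
                  soo, soa, cl)
}

# dense-ODE reference for the undelayed 4th-order cascade driven by the
# sigmoid probe; dead time is applied afterwards as an exact shift
ode_cascade_reference <- function(params, t, slope_const = 20 / 3,
                                  center = 0.5) {
  w1 <- params$omega_nm; z1 <- params$zeta_nm
  w2 <- params$omega_ms; z2 <- params$zeta_ms
  K1 <- params$k_nm; K2 <- params$k_ms
  rhs <- function(tt, x, p) {
    u <- 1 / (1 + exp(slope_const * (tt - center)))
    list(c(x[2], w1^2 * (K1 * u - x[1]) - 2 * z1 * w1 * x[2],
           x[4], w2^2 * (K2 * x[1] - x[3]) - 2 * z2 * w2 * x[4]))
  }
  out <- deSolve::ode(c(0, 0, 0, 0), t, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  out[, 4]
}

shift_zero_pad <- function(x, n_shift) {
  if (n_shift == 0) return(x)
  c(rep(0, n_shift), x)[seq_along(x)]
}
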