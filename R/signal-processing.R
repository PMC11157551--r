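#' EMG acquisition filter specification
#'
#' Describes the fixed filter chain applied to raw surface EMG before it is
#' converted to percent-MVC activation: a high-pass / low-pass acquisition
#' band, full-wave rectification, and an envelope low-pass. Two acquisition
#' profiles are built in, mirroring the two amplifiers used across the study:
#' `"web5000"` (10--100 Hz band) and `"ebm102"` (10--120 Hz band). Both use a
#' 22 Hz envelope low-pass.
#'
#' Filters are second-order Butterworth sections by default, applied causally
#' (`causal = TRUE`) because the original system ran in real time; set
#' `causal = FALSE` for zero-phase (forward-backward) filtering in offline
#' analyses.
#'
#' @param hp_hz High-pass cutoff in Hz. Default 10.
#' @param lp_hz Low-pass cutoff in Hz. Defaults to 100 for profile
#'   `"web5000"`, 120 for `"ebm102"`.
#' @param env_lp_hz Envelope low-pass cutoff in Hz applied after
#'   rectification. Default 22.
#' @param order Butterworth filter order per section. Default 2.
#' @param causal If `TRUE` (default), filters run forward only so that the
#'   output at time t depends only on inputs at times <= t.
#' @param profile Acquisition profile, `"web5000"` or `"ebm102"`; sets the
#'   default `lp_hz`.
#' @return An object of class `filter_spec`.
#' @examples
#' filter_spec()                      # 10-100 Hz band, 22 Hz envelope
#' filter_spec(profile = "ebm102")    # 10-120 Hz band
#' @export
filter_spec <- function(hp_hz = 10, lp_hz = NULL, env_lp_hz = 22, order = 2,
                        causal = TRUE, profile = c("web5000", "ebm102")) {
  profile <- match.arg(profile)
  if (is.null(lp_hz)) lp_hz <- switch(profile, web5000 = 100, ebm102 = 120)
  if (!is.numeric(hp_hz) || hp_hz <= 0) {
    abort("`hp_hz` must be a positive number.", class = "emgavatar_config_error")
  }
  if (!is.numeric(lp_hz) || lp_hz <= hp_hz) {
    abort("`lp_hz` must exceed `hp_hz`.", class = "emgavatar_config_error")
  }
  if (!is.numeric(env_lp_hz) || env_lp_hz <= 0) {
    abort("`env_lp_hz` must be a positive number.", class = "emgavatar_config_error")
  }
  if (!is.numeric(order) || order < 1 || order != round(order)) {
    abort("`order` must be a positive integer.", class = "emgavatar_config_error")
  }
  structure(
    list(hp_hz = hp_hz, lp_hz = lp_hz, env_lp_hz = env_lp_hz,
         order = as.integer(order), causal = isTRUE(causal), profile = profile),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf(
    "<filter_spec> profile=%s band=%g-%g Hz envelope=%g Hz order=%d %s\n",
    x$profile, x$hp_hz, x$lp_hz, x$env_lp_hz, x$order,
    if (x$causal) "causal" else "zero-phase"))
  invisible(x)
}

# sample rate from a uniform time column; errors on non-uniform spacing
infer_sample_rate <- function(time_s, tol = 1e-6) {
  if (length(time_s) < 2) {
    abort("Need at least two samples to infer a sample rate.",
          class = "emgavatar_format_error")
  }
  dt <- diff(time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > tol * median(dt)) {
    abort("Time base must be strictly increasing and uniform.",
          class = "emgavatar_format_error")
  }
  1 / median(dt)
}

check_spec_vs_rate <- function(spec, sample_rate) {
  nyq <- sample_rate / 2
  if (spec$lp_hz >= nyq || spec$env_lp_hz >= nyq) {
    abort(sprintf(
      "Filter cutoffs (lp=%g, env=%g Hz) must be below the Nyquist frequency (%g Hz).",
      spec$lp_hz, spec$env_lp_hz, nyq), class = "emgavatar_config_error")
  }
  invisible(TRUE)
}

apply_butter <- function(x, cutoff_hz, sample_rate, type, order, causal) {
  filt <- signal::butter(order, cutoff_hz / (sample_rate / 2), type = type)
  if (causal) {
    as.numeric(signal::filter(filt, x))
  } else {
    as.numeric(signal::filtfilt(filt, x))
  }
}

band_filter_channel <- function(x, spec, sample_rate) {
  x <- apply_butter(x, spec$hp_hz, sample_rate, "high", spec$order, spec$causal)
  apply_butter(x, spec$lp_hz, sample_rate, "low", spec$order, spec$causal)
}

envelope_channel <- function(x, spec, sample_rate) {
  # envelope of an already-rectified signal; clamp tiny causal undershoot
  pmax(apply_butter(x, spec$env_lp_hz, sample_rate, "low", spec$order, spec$causal), 0)
}

#' Band-pass filter and rectify raw EMG
#'
#' Applies the acquisition band (high-pass then low-pass Butterworth
#' sections) to both EMG channels and full-wave rectifies the result.
#'
#' @param data A data frame with columns `time_s`, `emg_extensor`,
#'   `emg_flexor`; `time_s` must be uniform.
#' @param spec A [filter_spec()].
#' @return A tibble with the same columns, band-passed and rectified
#'   (all EMG values >= 0).
#' @examples
#' rec <- tibble::tibble(time_s = seq(0, 1, by = 1e-3),
#'                       emg_extensor = sin(2 * pi * 50 * seq(0, 1, by = 1e-3)),
#'                       emg_flexor   = 0)
#' filtered <- emg_bandpass_rectify(rec, filter_spec())
#' @export
emg_bandpass_rectify <- function(data, spec = filter_spec()) {
  check_emg_frame(data)
  fs <- infer_sample_rate(data$time_s)
  check_spec_vs_rate(spec, fs)
  tibble(
    time_s = data$time_s,
    emg_extensor = abs(band_filter_channel(data$emg_extensor, spec, fs)),
    emg_flexor = abs(band_filter_channel(data$emg_flexor, spec, fs))
  )
}

check_emg_frame <- function(data) {
  need <- c("time_s", "emg_extensor", "emg_flexor")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("Missing EMG column(s): ", paste(missing, collapse = ", ")),
          class = "emgavatar_format_error")
  }
  invisible(TRUE)
}

#' Maximal-voluntary-contraction calibration
#'
#' Holds the envelope amplitude of each channel at maximal voluntary
#' contraction (MVC); activations are expressed as a percentage of these
#' values.
#'
#' @param mvc_extensor,mvc_flexor Strictly positive envelope amplitudes at
#'   MVC, in raw signal units.
#' @return An object of class `mvc_calibration`.
#' @seealso [mvc_from_recording()] to estimate the calibration from an MVC
#'   recording.
#' @export
mvc_calibration <- function(mvc_extensor, mvc_flexor) {
  if (!is.numeric(mvc_extensor) || !is.numeric(mvc_flexor) ||
      mvc_extensor <= 0 || mvc_flexor <= 0) {
    abort("MVC values must be strictly positive.",
          class = "emgavatar_calibration_error")
  }
  structure(list(mvc_extensor = mvc_extensor, mvc_flexor = mvc_flexor),
            class = "mvc_calibration")
}

#' Estimate MVC calibration from an MVC recording
#'
#' Runs the full envelope chain (band-pass, rectify, envelope low-pass) on a
#' recording made at maximal voluntary contraction and takes, per channel,
#' either the maximum (`"max"`, default) or the 95th percentile (`"p95"`,
#' robust to transient spikes) of the envelope.
#'
#' @param data MVC recording, same layout as for [emg_bandpass_rectify()].
#' @param spec A [filter_spec()].
#' @param method `"max"` or `"p95"`.
#' @return An [mvc_calibration()].
#' @export
mvc_from_recording <- function(data, spec = filter_spec(),
                               method = c("max", "p95")) {
  method <- match.arg(method)
  check_emg_frame(data)
  fs <- infer_sample_rate(data$time_s)
  check_spec_vs_rate(spec, fs)
  rect <- emg_bandpass_rectify(data, spec)
  env_e <- envelope_channel(rect$emg_extensor, spec, fs)
  env_f <- envelope_channel(rect$emg_flexor, spec, fs)
  pick <- function(x) switch(method, max = max(x), p95 = quantile(x, 0.95, names = FALSE))
  mvc_calibration(pick(env_e), pick(env_f))
}

#' Convert raw EMG to percent-MVC activation
#'
#' Full signal chain: acquisition band-pass, full-wave rectification, 22 Hz
#' envelope low-pass, then normalization to percent of the MVC calibration.
#'
#' @inheritParams emg_bandpass_rectify
#' @param cal An [mvc_calibration()].
#' @return A tibble with columns `time_s`, `m_e` (extensor %MVC) and `m_f`
#'   (flexor %MVC); both are >= 0 everywhere.
#' @export
emg_activation <- function(data, spec = filter_spec(), cal) {
  if (!inherits(cal, "mvc_calibration")) {
    abort("`cal` must be an mvc_calibration object.",
          class = "emgavatar_calibration_error")
  }
  check_emg_frame(data)
  fs <- infer_sample_rate(data$time_s)
  check_spec_vs_rate(spec, fs)
  rect <- emg_bandpass_rectify(data, spec)
  tibble(
    time_s = data$time_s,
    m_e = 100 * envelope_channel(rect$emg_extensor, spec, fs) / cal$mvc_extensor,
    m_f = 100 * envelope_channel(rect$emg_flexor, spec, fs) / cal$mvc_flexor
  )
}

# last-observation-carried-forward with an explicit initial value
na_locf <- function(x, init) {
  idx <- cumsum(!is.na(x))
  filled <- c(init, x[!is.na(x)])[idx + 1]
  filled
}

#' Agonist-antagonist ratio and sum
#'
#' Computes, per sample, the AA ratio \eqn{r = m_e / (m_f + m_e)} (the
#' equilibrium-point-like motor command that drives the avatar joint), the AA
#' sum `s = m_f + m_e` (co-contraction level, related to joint stiffness),
#' and the deviation `delta_r = r - baseline_r` that is fed to the joint
#' dynamics model.
#'
#' The ratio is undefined when both muscles are silent; wherever
#' `s < eps` the ratio is held at its last defined value (or at
#' `baseline_r` if no sample has been defined yet).
#'
#' @param data A data frame with columns `m_e` and `m_f` (percent MVC), e.g.
#'   the output of [emg_activation()].
#' @param baseline_r Resting AA ratio mapped to the avatar's standard
#'   position. Default 0.5 (balanced co-contraction at the 90 degree
#'   standard position).
#' @param eps Co-contraction threshold in %MVC below which the ratio is held
#'   rather than computed. Default 0.5.
#' @return The input tibble with columns `r`, `s` and `delta_r` added.
#'   Wherever `s >= eps`, \eqn{r \cdot s = m_e} and \eqn{(1 - r) s = m_f}.
#' @examples
#' act <- tibble::tibble(m_e = c(20, 30, 0), m_f = c(20, 10, 0))
#' compute_aa(act)   # r = 0.5, 0.75, then held at 0.75
#' @export
compute_aa <- function(data, baseline_r = 0.5, eps = 0.5) {
  if (!all(c("m_e", "m_f") %in% names(data))) {
    abort("`data` must have columns `m_e` and `m_f`.",
          class = "emgavatar_format_error")
  }
  if (!is.numeric(eps) || eps <= 0) {
    abort("`eps` must be > 0.", class = "emgavatar_config_error")
  }
  if (!is.numeric(baseline_r) || baseline_r < 0 || baseline_r > 1) {
    abort("`baseline_r` must lie in [0, 1].", class = "emgavatar_config_error")
  }
  s <- data$m_f + data$m_e
  r_raw <- ifelse(s >= eps, data$m_e / s, NA_real_)
  r <- na_locf(r_raw, init = baseline_r)
  as_tibble(data) |>
    mutate(r = r, s = s, delta_r = r - baseline_r)
}
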