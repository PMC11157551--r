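#' Sigmoid AA-ratio test input
#'
#' The decaying logistic input used to probe the joint dynamics:
#' \deqn{\Delta r(t) = \frac{1}{1 + \exp(c (t - t_0))}}
#' with slope constant `c = 20/3` 1/s and centre `t_0 = 0.5` s by default.
#' The curve starts near 1, passes exactly through 0.5 at the centre (its
#' inflection point) and decays towards 0.
#'
#' @param duration Duration in seconds; must be positive.
#' @param sim_rate Sample rate in Hz.
#' @param slope_const Logistic slope constant in 1/s.
#' @param center Inflection time in seconds.
#' @return A tibble with columns `time_s` and `delta_r`.
#' @examples
#' sig <- sigmoid_input(duration = 2)
#' sig$delta_r[sig$time_s == 0.5]  # 0.5
#' @export
sigmoid_input <- function(duration = 2, sim_rate = 1000,
                          slope_const = 20 / 3, center = 0.5) {
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be positive.", class = "emgavatar_usage_error")
  }
  time_s <- seq(0, duration - 1 / sim_rate, by = 1 / sim_rate)
  tibble(time_s = time_s,
         delta_r = 1 / (1 + exp(slope_const * (time_s - center))))
}

#' Target activation profile for synthetic EMG
#'
#' Defines the per-sample %MVC envelopes that [synth_emg()] should realize.
#' Envelopes can be given as constants, vectors of the right length, or
#' functions of time.
#'
#' @param duration Duration in seconds.
#' @param sim_rate Sample rate in Hz.
#' @param m_e,m_f Extensor / flexor envelope in %MVC: a single number, a
#'   numeric vector with one value per sample, or a function of time
#'   (seconds).
#' @return A tibble with columns `time_s`, `m_e`, `m_f`.
#' @export
activation_profile <- function(duration, sim_rate = 1000, m_e = 0, m_f = 0) {
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be positive.", class = "emgavatar_usage_error")
  }
  time_s <- seq(0, duration - 1 / sim_rate, by = 1 / sim_rate)
  expand_env <- function(env) {
    out <- if (is.function(env)) env(time_s)
           else if (length(env) == 1L) rep(env, length(time_s))
           else env
    if (length(out) != length(time_s)) {
      abort("Envelope length must match the time grid.",
            class = "emgavatar_usage_error")
    }
    if (any(out < 0)) {
      abort("Envelopes must be non-negative.", class = "emgavatar_usage_error")
    }
    out
  }
  tibble(time_s = time_s, m_e = expand_env(m_e), m_f = expand_env(m_f))
}

# Band-limited unit-variance carriers. The "noise" carrier is the classic
# surface-EMG surrogate (band-limited Gaussian noise); its sub-12 Hz
# intensity drift is divided out so the short-time intensity tracks the
# commanded envelope rather than the carrier's own random walk. The
# "chirp" carrier is a constant-modulus triangular frequency sweep across
# the same band (random initial phase): spectrally similar, with an
# intensity so stable that envelope recovery is limited only by the
# processing chain itself.
emg_carrier <- function(n, sample_rate, noise_band, order = 2,
                        type = c("noise", "chirp")) {
  type <- match.arg(type)
  if (type == "noise") {
    x <- rnorm(n + 2000)  # pad to flush the filter transient
    filt_l <- signal::butter(order, noise_band[2] / (sample_rate / 2), "low")
    filt_h <- signal::butter(order, noise_band[1] / (sample_rate / 2), "high")
    x <- as.numeric(signal::filter(filt_l, as.numeric(signal::filter(filt_h, x))))
    x <- x[-(1:2000)]
    slow_lp <- signal::butter(2, min(12, noise_band[1] / 2 + 2) / (sample_rate / 2),
                              "low")
    slow <- as.numeric(signal::filtfilt(slow_lp, abs(x)))
    x <- x / pmax(slow, 0.25 * median(slow))
  } else {
    t <- (seq_len(n) - 1) / sample_rate
    sweep_hz <- 7
    tri <- abs(2 * ((t * sweep_hz) %% 1) - 1)
    f_inst <- noise_band[1] + (noise_band[2] - noise_band[1]) * tri
    x <- sin(2 * pi * cumsum(f_inst) / sample_rate + runif(1, 0, 2 * pi))
  }
  x / sd(x)
}

#' Synthesize raw surface EMG with a known activation envelope
#'
#' Standard surrogate surface-EMG model: a band-limited zero-mean Gaussian
#' noise carrier (default 20--90 Hz) amplitude-modulated by the target
#' %MVC envelope. The modulation constant is calibrated against the exact
#' processing chain in `spec`, so running the result through
#' [emg_activation()] recovers the commanded envelope (up to filter
#' transients and the stochastic envelope ripple).
#'
#' @param profile An [activation_profile()].
#' @param cal An [mvc_calibration()] giving the envelope amplitude that
#'   corresponds to 100 %MVC on each channel.
#' @param noise_band Carrier band in Hz, default `c(20, 90)`.
#' @param seed Integer seed; the recording is deterministic given the seed.
#' @param spec The [filter_spec()] the consumer pipeline will use; the
#'   modulation constant is calibrated against it.
#' @param carrier `"noise"` (default): intensity-stabilized band-limited
#'   Gaussian noise, the standard surface-EMG surrogate; `"chirp"`: a
#'   constant-modulus frequency sweep across the band, for calibration
#'   work where envelope-recovery error must come from the processing
#'   chain alone.
#' @return A raw-EMG tibble with columns `time_s`, `emg_extensor`,
#'   `emg_flexor`.
#' @export
synth_emg <- function(profile, cal = mvc_calibration(1, 1),
                      noise_band = c(20, 90), seed = 1,
                      spec = filter_spec(), carrier = c("noise", "chirp")) {
  carrier <- match.arg(carrier)
  if (!is.data.frame(profile) || !nrow(profile)) {
    abort("`profile` must be a non-empty activation profile.",
          class = "emgavatar_usage_error")
  }
  stopifnot(all(c("time_s", "m_e", "m_f") %in% names(profile)))
  fs <- infer_sample_rate(profile$time_s)
  n <- nrow(profile)
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    code
  }
  withr_seed({
    carrier_e <- emg_carrier(n, fs, noise_band, spec$order, carrier)
    carrier_f <- emg_carrier(n, fs, noise_band, spec$order, carrier)
    calib <- emg_carrier(max(n, 6000), fs, noise_band, spec$order, carrier)
  })
  # gain of the consumer chain on a unit-variance carrier with unit envelope
  rectified <- abs(band_filter_channel(calib, spec, fs))
  env <- envelope_channel(rectified, spec, fs)
  k <- mean(env[-seq_len(min(1000, length(env) %/% 2))])
  tibble(
    time_s = profile$time_s,
    emg_extensor = carrier_e * profile$m_e / 100 * cal$mvc_extensor / k,
    emg_flexor = carrier_f * profile$m_f / 100 * cal$mvc_flexor / k
  )
}

# smallest dummy count >= 1 closing the preliminary block structure
# (blocks of three rated slots after each standard exposure, final block of
# two): total slots must be 2 (mod 3)
preliminary_dummy_count <- function(n_comparison_trials) {
  d <- 1
  while ((n_comparison_trials + d) %% 3 != 2) d <- d + 1
  d
}

#' Randomized experimental protocol
#'
#' Builds the ordered trial list of either experiment. Every comparison
#' setting appears exactly twice, in randomized order, with dummy trials
#' (the standard setting presented as a comparison) inserted uniformly at
#' random among the rated slots.
#'
#' * `"preliminary"`: each standard exposure is followed by a block of three
#'   rated comparison slots; the final block holds two. The dummy count
#'   defaults to the smallest positive number that closes this block
#'   structure (3 for a four-setting catalog).
#' * `"main"`: strict alternation, one rated comparison slot after each
#'   standard exposure; one dummy by default.
#'
#' @param kind `"preliminary"` or `"main"`.
#' @param catalog A [nmss_catalog()] (or compatible `settings_catalog`).
#' @param seed Integer seed; the ordering is reproducible given the seed.
#' @param n_dummy Number of dummy trials; `NULL` for the kind-specific
#'   default described above.
#' @return A `protocol_plan` tibble with columns `trial`, `phase`, `role`
#'   (`"standard"` exposure or `"comparison"` rated slot), `setting`,
#'   `repetition` and `is_dummy`.
#' @examples
#' plan <- make_protocol("main", nmss_catalog("main_omega"), seed = 1)
#' table(plan$setting[plan$role == "comparison"])
#' @export
make_protocol <- function(kind = c("preliminary", "main"), catalog, seed = 1,
                          n_dummy = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(catalog, "settings_catalog"))
  comp_names <- names(catalog$comparisons)
  if (length(comp_names) < 2) {
    abort("Catalog must contain at least two comparison settings.",
          class = "emgavatar_config_error")
  }
  n_rated <- 2L * length(comp_names)
  if (is.null(n_dummy)) {
    n_dummy <- if (kind == "preliminary") preliminary_dummy_count(n_rated) else 1L
  }
  slots <- c(rep(comp_names, each = 2L), rep("dummy", n_dummy))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  slots <- sample(slots)
  block_sizes <- if (kind == "preliminary") {
    n_full <- (length(slots) - 2L) %/% 3L
    if (n_full * 3L + 2L != length(slots)) {
      abort("Slot count does not close the preliminary block structure; adjust `n_dummy`.",
            class = "emgavatar_config_error")
    }
    c(rep(3L, n_full), 2L)
  } else {
    rep(1L, length(slots))
  }
  rows <- list()
  trial <- 0L
  idx <- 1L
  rep_count <- setNames(integer(length(comp_names) + 1L), c(comp_names, "dummy"))
  for (phase in seq_along(block_sizes)) {
    trial <- trial + 1L
    rows[[length(rows) + 1L]] <- tibble(
      trial = trial, phase = phase, role = "standard",
      setting = "standard", repetition = NA_integer_, is_dummy = FALSE)
    for (j in seq_len(block_sizes[phase])) {
      nm <- slots[idx]; idx <- idx + 1L
      rep_count[nm] <- rep_count[nm] + 1L
      trial <- trial + 1L
      rows[[length(rows) + 1L]] <- tibble(
        trial = trial, phase = phase, role = "comparison",
        setting = nm, repetition = rep_count[[nm]], is_dummy = nm == "dummy")
    }
  }
  out <- list_rbind(rows)
  structure(out, class = c("protocol_plan", class(out)),
            kind = kind, catalog = catalog$name, seed = seed)
}

#' Virtual questionnaire participants
#'
#' Generates per-participant, per-characteristic response curves over the
#' comparison settings of a catalog. Each curve is a Gaussian bump over the
#' setting index: `floor + (height - floor) * exp(-(i - peak)^2 / (2 w^2))`,
#' with the peak location drawn per participant (the individual "preferred
#' dynamics"), plus an additive rating noise scale. All true responses lie
#' in \[-3, 3\].
#'
#' @param n Number of participants (the study used 6 per experiment).
#' @param settings Character vector of comparison setting names, in
#'   catalog order.
#' @param seed Integer seed.
#' @param noise_sd Rating noise standard deviation (0 for noiseless raters).
#' @param floor_range,height_range,width_range Ranges the per-curve floor,
#'   peak height and peak width are drawn from.
#' @return A `virtual_participants` tibble with one row per participant and
#'   characteristic (`soo`, `soa`, `cl`): columns `participant_id`,
#'   `characteristic`, `peak_loc`, `peak_width`, `floor`, `height`,
#'   `noise_sd`.
#' @export
virtual_participants <- function(n = 6, settings, seed = 1, noise_sd = 0.35,
                                 floor_range = c(-2.5, -1),
                                 height_range = c(1.5, 2.8),
                                 width_range = c(0.8, 1.6)) {
  stopifnot(is.character(settings), length(settings) >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  chars <- c("soo", "soa", "cl")
  grid <- expand_grid(participant_id = seq_len(n), characteristic = chars)
  k <- nrow(grid)
  out <- grid |>
    mutate(
      peak_loc = runif(k, 1, length(settings)),
      peak_width = runif(k, width_range[1], width_range[2]),
      floor = runif(k, floor_range[1], floor_range[2]),
      height = runif(k, height_range[1], height_range[2]),
      noise_sd = noise_sd
    )
  structure(out, class = c("virtual_participants", class(out)),
            settings = settings, seed = seed)
}

# project a continuous rating onto the questionnaire scale:
# clip to [-3, 3], round to the nearest 0.25
quantize_rating <- function(x) {
  round(pmin(3, pmax(-3, x)) * 4) / 4
}

#' True response curves of virtual participants
#'
#' Evaluates each participant's underlying response curve at every
#' comparison setting, both as the continuous truth and projected onto the
#' questionnaire scale (clipped to \[-3, 3\] and rounded to 0.25 steps) --
#' the latter is what a noiseless rater would report, and its argmax defines
#' the participant's true peak setting(s).
#'
#' @param participants A [virtual_participants()] tibble.
#' @return A tibble with columns `participant_id`, `characteristic`,
#'   `setting`, `true_value`, `scale_value`.
#' @export
participant_truth <- function(participants) {
  stopifnot(inherits(participants, "virtual_participants"))
  settings <- attr(participants, "settings")
  participants |>
    as_tibble() |>
    expand_grid(setting_idx = seq_along(settings)) |>
    mutate(
      setting = settings[.data$setting_idx],
      true_value = .data$floor + (.data$height - .data$floor) *
        exp(-(.data$setting_idx - .data$peak_loc)^2 / (2 * .data$peak_width^2)),
      scale_value = quantize_rating(.data$true_value)
    ) |>
    select("participant_id", "characteristic", "setting",
           "true_value", "scale_value")
}

#' Synthesize questionnaire ratings
#'
#' Simulates every rated trial of a protocol for every virtual participant:
#' rating = true curve value + Gaussian noise, clipped to \[-3, 3\] and
#' rounded to the nearest 0.25 (the questionnaire scale, relative to the
#' standard setting at 0). Dummy trials have true value 0.
#'
#' @param participants A [virtual_participants()] tibble.
#' @param plan A [make_protocol()] plan whose comparison settings match the
#'   participants' settings.
#' @param seed Integer seed for the rating noise.
#' @return A ratings tibble with columns `participant_id`, `experiment`,
#'   `setting`, `repetition`, `soo`, `soa`, `cl`.
#' @export
synth_ratings <- function(participants, plan, seed = 1) {
  stopifnot(inherits(participants, "virtual_participants"),
            inherits(plan, "protocol_plan"))
  settings <- attr(participants, "settings")
  slots <- plan |> filter(.data$role == "comparison")
  bad <- setdiff(unique(slots$setting), c(settings, "dummy"))
  if (length(bad)) {
    abort(paste0("Plan contains settings unknown to the participants: ",
                 paste(bad, collapse = ", ")),
          class = "emgavatar_config_error")
  }
  truth <- participant_truth(participants) |>
    select("participant_id", "characteristic", "setting", "true_value")
  noise_tbl <- participants |>
    as_tibble() |>
    select("participant_id", "characteristic", "noise_sd")
  long <- expand_grid(participant_id = unique(participants$participant_id),
                      slots) |>
    expand_grid(characteristic = c("soo", "soa", "cl")) |>
    left_join(truth, by = c("participant_id", "characteristic", "setting")) |>
    left_join(noise_tbl, by = c("participant_id", "characteristic")) |>
    mutate(true_value = ifelse(.data$is_dummy, 0, .data$true_value))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  long <- long |>
    mutate(value = quantize_rating(.data$true_value +
                                     rnorm(n(), 0, .data$noise_sd)))
  long |>
    select("participant_id", "setting", "repetition", "characteristic",
           "value") |>
    pivot_wider(names_from = "characteristic", values_from = "value") |>
    mutate(experiment = attr(plan, "kind"), .after = "participant_id") |>
    arrange(.data$participant_id, .data$setting, .data$repetition)
}
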