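#' Cross-correlation lag between two series
#'
#' Operationalizes "delay" as the argmax of the normalized cross-correlation
#' over lags within `+- max_lag`, at sample resolution (optionally refined
#' by parabolic interpolation around the peak). Positive lag means `test`
#' trails `reference`; a lead shows up as a negative lag.
#'
#' @param reference,test Equal-length numeric series at the same rate.
#' @param rate Sample rate in Hz.
#' @param max_lag Maximum absolute lag searched, in seconds; must be less
#'   than half the series duration.
#' @param sub_sample If `TRUE`, refine the integer-sample argmax by fitting
#'   a parabola through the three correlations around the peak. Off by
#'   default; sample resolution suffices at 1 kHz.
#' @return Lag in seconds.
#' @examples
#' x <- sin(2 * pi * seq(0, 2, by = 1e-3))
#' y <- c(rep(0, 300), x)[seq_along(x)]
#' estimate_lag(x, y, rate = 1000)  # 0.3
#' @export
estimate_lag <- function(reference, test, rate, max_lag = 0.5,
                         sub_sample = FALSE) {
  n <- length(reference)
  if (length(test) != n) {
    abort("Series must have equal length.", class = "emgavatar_usage_error")
  }
  if (max_lag >= n / rate / 2) {
    abort("`max_lag` must be less than half the series duration.",
          class = "emgavatar_usage_error")
  }
  if (sd(reference) == 0 || sd(test) == 0) {
    abort("Lag is undefined for a constant series.",
          class = "emgavatar_undefined_lag_error")
  }
  m <- floor(max_lag * rate)
  lags <- (-m):m
  cors <- vapply(lags, function(k) {
    if (k >= 0) {
      a <- test[(1 + k):n]; b <- reference[1:(n - k)]
    } else {
      a <- test[1:(n + k)]; b <- reference[(1 - k):n]
    }
    if (sd(a) == 0 || sd(b) == 0) return(-Inf)
    cor(a, b)
  }, numeric(1))
  i <- which.max(cors)
  lag <- lags[i]
  if (sub_sample && i > 1 && i < length(lags) && all(is.finite(cors[(i - 1):(i + 1)]))) {
    c0 <- cors[i - 1]; c1 <- cors[i]; c2 <- cors[i + 1]
    denom <- c0 - 2 * c1 + c2
    if (denom < 0) lag <- lag + 0.5 * (c0 - c2) / denom
  }
  lag / rate
}

#' Measured DC gain of a setting
#'
#' Drives the cascade with a constant unit input until well past ten time
#' constants of its slowest section and returns the asymptotic output
#' (degrees per unit input). For any valid parameters this converges to the
#' analytic final value `k_nm * k_ms`.
#'
#' @param setting An [avatar_setting()] or [nmss_params()].
#' @param sim_rate Simulation rate in Hz.
#' @return Dimensionless steady-state gain (degrees per unit input).
#' @examples
#' dc_gain_of(standard_setting_of())  # ~300
#' @export
dc_gain_of <- function(setting, sim_rate = 1000) {
  params <- if (inherits(setting, "avatar_setting")) setting$params else setting
  stopifnot(inherits(params, "nmss_params"))
  duration <- params$l_nm + params$l_ms + 14 / slowest_decay_rate(params)
  casc <- build_cascade(params, sim_rate)
  n <- ceiling(duration * sim_rate)
  y <- nmss_simulate(casc, rep(1, n))
  y_end <- tail(y, 1)
  if (!is.finite(y_end)) {
    abort("Simulation did not settle; check the parameters.",
          class = "emgavatar_convergence_error")
  }
  y_end
}

#' Analytic low-frequency group delay of a setting
#'
#' Closed-form alternative delay metric: the group delay of the cascade at
#' DC, `2 zeta_nm / omega_nm + 2 zeta_ms / omega_ms + l_nm + l_ms` seconds.
#' Useful as a cross-check on the cross-correlation lag; the
#' cross-correlation figure is the canonical one reported by
#' [characterize_catalog()].
#'
#' @inheritParams dc_gain_of
#' @return Group delay at DC in seconds.
#' @export
dc_group_delay <- function(setting) {
  params <- if (inherits(setting, "avatar_setting")) setting$params else setting
  stopifnot(inherits(params, "nmss_params"))
  2 * params$zeta_nm / params$omega_nm + 2 * params$zeta_ms / params$omega_ms +
    params$l_nm + params$l_ms
}

# slowest pole decay rate of the cascade (rad/s): for an overdamped
# section the slow real pole w (zeta - sqrt(zeta^2 - 1)) governs settling,
# not zeta * w
slowest_decay_rate <- function(params) {
  section_rate <- function(w, z) if (z >= 1) w * (z - sqrt(z^2 - 1)) else z * w
  min(section_rate(params$omega_nm, params$zeta_nm),
      section_rate(params$omega_ms, params$zeta_ms))
}

# overshoot of the unit-step response: (peak - steady state) / steady state
step_overshoot <- function(params, sim_rate) {
  n <- ceiling((params$l_nm + params$l_ms + 14 / slowest_decay_rate(params)) *
                 sim_rate)
  y <- nmss_simulate(build_cascade(params, sim_rate), rep(1, n))
  ss <- tail(y, 1)
  max(0, (max(y) - ss) / ss)
}

#' Characterize every setting of a catalog
#'
#' Simulates the standard setting and every comparison setting on a common
#' input (the sigmoid probe by default) and summarises each response
#' against the standard-setting output: cross-correlation lag (positive =
#' trails the standard; negative = leads it, the negative-delay regime
#' reached at high natural angular frequency), measured DC gain, and
#' unit-step overshoot.
#'
#' @param catalog A [nmss_catalog()] result.
#' @param input A data frame with a `delta_r` column, e.g.
#'   [sigmoid_input()]; sampled at `sim_rate`.
#' @param sim_rate Simulation rate in Hz.
#' @param max_lag Lag search window in seconds (see [estimate_lag()]).
#' @param sub_sample Passed to [estimate_lag()].
#' @return A `response_catalog` tibble with columns `setting`, `lag_s`,
#'   `dc_gain`, `overshoot`, `reference`.
#' @examples
#' \donttest{
#' characterize_catalog(nmss_catalog("preliminary_deadtime"))
#' }
#' @export
characterize_catalog <- function(catalog, input = sigmoid_input(),
                                 sim_rate = 1000, max_lag = 0.5,
                                 sub_sample = FALSE) {
  stopifnot(inherits(catalog, "settings_catalog"))
  u <- input$delta_r
  ref <- nmss_simulate(build_cascade(catalog$standard$params, sim_rate), u)
  all_settings <- c(list(standard = catalog$standard), catalog$comparisons)
  out <- imap(all_settings, function(st, nm) {
    y <- nmss_simulate(build_cascade(st$params, sim_rate), u)
    tibble(
      setting = nm,
      lag_s = estimate_lag(ref, y, sim_rate, max_lag, sub_sample),
      dc_gain = dc_gain_of(st, sim_rate),
      overshoot = step_overshoot(st$params, sim_rate),
      reference = "standard"
    )
  }) |> list_rbind()
  structure(out, class = c("response_catalog", class(out)),
            catalog = catalog$name)
}

#' @export
autoplot.response_catalog <- function(object, ...) {
  df <- mutate(object, setting = factor(.data$setting,
                                        levels = object$setting))
  ggplot(df, aes(x = .data$setting, y = 1000 * .data$lag_s)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Lag vs standard [ms]",
         title = paste0("Response lags (catalog: ", attr(object, "catalog"), ")"),
         subtitle = "Negative bars: the setting leads the standard dynamics") +
    theme_minimal()
}
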