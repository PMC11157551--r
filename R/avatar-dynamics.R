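#' NMSS model parameters
#'
#' The neuromusculoskeletal (NMSS) model of elbow-joint control is a cascade
#' of two second-order transfer functions, the neuromuscular (NM) system with
#' dead time and the musculoskeletal (MS) system:
#' \deqn{G_{NM}(s) = K_{NM} \frac{\omega_{nNM}^2}{s^2 + 2\zeta_{NM}\omega_{nNM} s + \omega_{nNM}^2} e^{-L_{NM} s}}
#' \deqn{G_{MS}(s) = K_{MS} \frac{\omega_{nMS}^2}{s^2 + 2\zeta_{MS}\omega_{nMS} s + \omega_{nMS}^2}}
#' The cascade maps the agonist-antagonist ratio deviation (dimensionless) to
#' angular displacement in degrees; its DC gain is `k_nm * k_ms` degrees per
#' unit input.
#'
#' @param k_nm,k_ms Gains of the NM and MS sections. Only the product is
#'   observable in the output.
#' @param omega_nm,omega_ms Natural angular frequencies in rad/s; must be
#'   positive. Low values produce phase delay, high values let the avatar
#'   lead its reference ("negative delay").
#' @param zeta_nm,zeta_ms Damping coefficients (dimensionless, positive).
#' @param l_nm,l_ms Dead times in seconds (non-negative). The MS dead time
#'   defaults to 0; the total dead time `l_nm + l_ms` is what the simulation
#'   realizes.
#' @return An object of class `nmss_params`.
#' @examples
#' nmss_params(k_nm = 300, omega_nm = 6, omega_ms = 6)
#' @export
nmss_params <- function(k_nm = 300, k_ms = 1,
                        omega_nm = 6, omega_ms = 6,
                        zeta_nm = 0.7, zeta_ms = 0.7,
                        l_nm = 0, l_ms = 0) {
  vals <- c(k_nm = k_nm, k_ms = k_ms, omega_nm = omega_nm,
            omega_ms = omega_ms, zeta_nm = zeta_nm, zeta_ms = zeta_ms,
            l_nm = l_nm, l_ms = l_ms)
  if (!all(is.finite(vals))) {
    abort("All NMSS parameters must be finite.", class = "emgavatar_parameter_error")
  }
  if (omega_nm <= 0 || omega_ms <= 0) {
    abort("Natural angular frequencies must be positive.",
          class = "emgavatar_parameter_error")
  }
  if (zeta_nm <= 0 || zeta_ms <= 0) {
    abort("Damping coefficients must be positive.",
          class = "emgavatar_parameter_error")
  }
  if (l_nm < 0 || l_ms < 0) {
    abort("Dead times must be non-negative.", class = "emgavatar_parameter_error")
  }
  structure(as.list(vals), class = "nmss_params")
}

#' @export
print.nmss_params <- function(x, ...) {
  cat(sprintf(
    "<nmss_params> K=%g*%g omega=(%g, %g) rad/s zeta=(%g, %g) L=(%g, %g) ms\n",
    x$k_nm, x$k_ms, x$omega_nm, x$omega_ms, x$zeta_nm, x$zeta_ms,
    1000 * x$l_nm, 1000 * x$l_ms))
  invisible(x)
}

#' A named avatar dynamics setting
#'
#' @param name Unique label within a catalog.
#' @param params An [nmss_params()] object.
#' @param provenance Free-text note on which experiment/catalog the setting
#'   belongs to.
#' @return An object of class `avatar_setting`.
#' @export
avatar_setting <- function(name, params, provenance = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!inherits(params, "nmss_params")) {
    abort("`params` must be an nmss_params object.",
          class = "emgavatar_parameter_error")
  }
  structure(list(name = name, params = params, provenance = provenance),
            class = "avatar_setting")
}

#' @export
print.avatar_setting <- function(x, ...) {
  cat(sprintf("<avatar_setting> \"%s\" (%s)\n", x$name, x$provenance))
  print(x$params)
  invisible(x)
}

standard_setting <- function() {
  avatar_setting("standard", nmss_params(), "standard setting")
}

#' Built-in avatar settings catalogs
#'
#' Three catalogs of comparison settings, each varying a single parameter
#' group from the shared standard setting (gain 300, natural angular
#' frequency 6 rad/s in both sections, damping 0.7, dead time 0):
#'
#' * `"preliminary_omega"`: natural angular frequency (both sections)
#'   `omega_np1..4` = 8, 6, 4, 2 rad/s.
#' * `"preliminary_deadtime"`: dead time `L_1..L_4` = 0, 50, 150, 300 ms.
#' * `"main_omega"`: natural angular frequency `omega_nm1..6` =
#'   72, 36, 18, 9, 4, 2 rad/s.
#'
#' @param name Catalog name.
#' @return An object of class `settings_catalog` with elements `standard`
#'   (an [avatar_setting()]), `comparisons` (named list of settings) and
#'   `name`.
#' @examples
#' cat <- nmss_catalog("main_omega")
#' catalog_setting(cat, "omega_nm1")$params$omega_nm  # 72
#' @export
nmss_catalog <- function(name = c("preliminary_omega", "preliminary_deadtime",
                                  "main_omega")) {
  name <- match.arg(name)
  std <- standard_setting()
  comparisons <- switch(
    name,
    preliminary_omega = {
      omegas <- c(omega_np1 = 8, omega_np2 = 6, omega_np3 = 4, omega_np4 = 2)
      imap(as.list(omegas), function(w, nm) {
        avatar_setting(nm, nmss_params(omega_nm = w, omega_ms = w),
                       "preliminary experiment (natural angular frequency)")
      })
    },
    preliminary_deadtime = {
      deadtimes_ms <- c(L_1 = 0, L_2 = 50, L_3 = 150, L_4 = 300)
      imap(as.list(deadtimes_ms), function(L, nm) {
        avatar_setting(nm, nmss_params(l_nm = L / 1000),
                       "preliminary experiment (dead time)")
      })
    },
    main_omega = {
      omegas <- c(omega_nm1 = 72, omega_nm2 = 36, omega_nm3 = 18,
                  omega_nm4 = 9, omega_nm5 = 4, omega_nm6 = 2)
      imap(as.list(omegas), function(w, nm) {
        avatar_setting(nm, nmss_params(omega_nm = w, omega_ms = w),
                       "main experiment (natural angular frequency)")
      })
    }
  )
  structure(list(standard = std, comparisons = comparisons, name = name),
            class = "settings_catalog")
}

#' @rdname nmss_catalog
#' @param catalog A `settings_catalog`.
#' @param setting Setting name; `"standard"` or one of the comparison names.
#' @export
catalog_setting <- function(catalog, setting) {
  stopifnot(inherits(catalog, "settings_catalog"))
  if (identical(setting, "standard")) return(catalog$standard)
  out <- catalog$comparisons[[setting]]
  if (is.null(out)) {
    abort(sprintf("Unknown setting \"%s\" in catalog \"%s\". Available: %s",
                  setting, catalog$name,
                  paste(c("standard", names(catalog$comparisons)), collapse = ", ")),
          class = "emgavatar_lookup_error")
  }
  out
}

#' @export
print.settings_catalog <- function(x, ...) {
  cat(sprintf("<settings_catalog> \"%s\": standard + %d comparison settings\n",
              x$name, length(x$comparisons)))
  cat(" ", paste(names(x$comparisons), collapse = ", "), "\n")
  invisible(x)
}

# First-order-hold discretization of one second-order unity-structure
# section K * w^2 / (s^2 + 2 z w s + w^2), via the Van Loan augmented
# matrix exponential. Returns the state transition and the two input
# weights (previous and current sample) of the triangle-hold update
#   x[k+1] = Phi x[k] + B1 u[k] + B2 u[k+1].
foh_section <- function(K, w, z, dt) {
  A <- matrix(c(0, -w^2, 1, -2 * z * w), 2, 2)
  B <- c(0, K * w^2)
  aug <- rbind(cbind(A, B, c(0, 0)), c(0, 0, 0, 1), c(0, 0, 0, 0))
  M <- as.matrix(Matrix::expm(aug * dt))
  Phi <- M[1:2, 1:2]
  G0 <- M[1:2, 3]   # int_0^dt e^{A(dt-s)} B ds
  G1 <- M[1:2, 4]   # int_0^dt e^{A(dt-s)} B s ds
  B2 <- G1 / dt
  B1 <- G0 - B2
  list(p11 = Phi[1, 1], p12 = Phi[1, 2], p21 = Phi[2, 1], p22 = Phi[2, 2],
       b1a = B1[1], b1b = B1[2], b2a = B2[1], b2b = B2[2])
}

#' Build the discrete NMSS cascade
#'
#' Discretizes the two second-order sections at the simulation rate using a
#' first-order (triangle) hold on the input of each section, realized in
#' state space via the augmented matrix exponential; the total dead time
#' `l_nm + l_ms` becomes an integer-sample FIFO of length
#' `round((l_nm + l_ms) * sim_rate)` on the cascade output. The DC gain of
#' the realization equals `k_nm * k_ms` exactly.
#'
#' @param params An [nmss_params()] object (or an [avatar_setting()], whose
#'   parameters are used).
#' @param sim_rate Simulation rate in Hz; at least 200.
#' @return An object of class `nmss_cascade`.
#' @export
build_cascade <- function(params, sim_rate = 1000) {
  if (inherits(params, "avatar_setting")) params <- params$params
  if (!inherits(params, "nmss_params")) {
    abort("`params` must be an nmss_params or avatar_setting object.",
          class = "emgavatar_parameter_error")
  }
  if (!is.numeric(sim_rate) || sim_rate < 200) {
    abort("`sim_rate` must be at least 200 Hz.", class = "emgavatar_parameter_error")
  }
  dt <- 1 / sim_rate
  structure(
    list(
      nm = foh_section(params$k_nm, params$omega_nm, params$zeta_nm, dt),
      ms = foh_section(params$k_ms, params$omega_ms, params$zeta_ms, dt),
      delay_n = as.integer(round((params$l_nm + params$l_ms) * sim_rate)),
      dc_gain = params$k_nm * params$k_ms,
      sim_rate = sim_rate,
      params = params
    ),
    class = "nmss_cascade"
  )
}

#' @export
print.nmss_cascade <- function(x, ...) {
  cat(sprintf("<nmss_cascade> at %g Hz, DC gain %g, delay %d samples\n",
              x$sim_rate, x$dc_gain, x$delay_n))
  invisible(x)
}

#' Streaming simulation of the NMSS cascade
#'
#' `nmss_init()` creates a fresh streaming state for a cascade;
#' `nmss_step()` consumes exactly one input sample and emits exactly one
#' output sample (degrees of angular displacement). Feeding a series sample
#' by sample reproduces [nmss_simulate()] bit for bit, and the output at
#' step k depends only on inputs up to step k.
#'
#' @param cascade An [build_cascade()] result.
#' @return `nmss_init()`: an `nmss_state` object. `nmss_step()`: a list with
#'   elements `state` (updated state) and `y` (output sample, degrees).
#' @examples
#' casc <- build_cascade(nmss_params(), sim_rate = 1000)
#' st <- nmss_init(casc)
#' out <- nmss_step(st, 0.1)
#' out$y
#' @export
nmss_init <- function(cascade) {
  stopifnot(inherits(cascade, "nmss_cascade"))
  structure(
    list(cascade = cascade,
         x1a = 0, x1b = 0, x2a = 0, x2b = 0,
         u_prev = 0, y1_prev = 0, started = FALSE,
         fifo = rep(0, cascade$delay_n), fifo_pos = 1L),
    class = "nmss_state"
  )
}

#' @rdname nmss_init
#' @param state An `nmss_state` from [nmss_init()].
#' @param u One input sample (dimensionless AA-ratio deviation).
#' @export
nmss_step <- function(state, u) {
  if (!inherits(state, "nmss_state")) {
    abort("`state` must come from nmss_init().", class = "emgavatar_usage_error")
  }
  if (length(u) != 1L || !is.finite(u)) {
    abort("`u` must be a single finite number.", class = "emgavatar_usage_error")
  }
  s1 <- state$cascade$nm
  s2 <- state$cascade$ms
  if (state$started) {
    y1a <- s1$p11 * state$x1a + s1$p12 * state$x1b + s1$b1a * state$u_prev + s1$b2a * u
    y1b <- s1$p21 * state$x1a + s1$p22 * state$x1b + s1$b1b * state$u_prev + s1$b2b * u
    state$x1a <- y1a; state$x1b <- y1b
    y1 <- y1a
    y2a <- s2$p11 * state$x2a + s2$p12 * state$x2b + s2$b1a * state$y1_prev + s2$b2a * y1
    y2b <- s2$p21 * state$x2a + s2$p22 * state$x2b + s2$b1b * state$y1_prev + s2$b2b * y1
    state$x2a <- y2a; state$x2b <- y2b
  } else {
    y1 <- 0
    state$started <- TRUE
  }
  y0 <- state$x2a
  d <- state$cascade$delay_n
  if (d > 0L) {
    pos <- state$fifo_pos
    y <- state$fifo[pos]
    state$fifo[pos] <- y0
    state$fifo_pos <- if (pos == d) 1L else pos + 1L
  } else {
    y <- y0
  }
  state$u_prev <- u
  state$y1_prev <- y1
  list(state = state, y = y)
}

#' Batch simulation of the NMSS cascade
#'
#' Runs the cascade over a full input series. Implemented as repeated
#' [nmss_step()] calls, so streaming and batch outputs are identical.
#'
#' @param cascade An [build_cascade()] result.
#' @param u Numeric input series (AA-ratio deviation per sample).
#' @return Numeric vector of angular displacements in degrees, same length
#'   as `u`.
#' @export
nmss_simulate <- function(cascade, u) {
  stopifnot(inherits(cascade, "nmss_cascade"))
  if (!length(u)) {
    abort("Input series is empty.", class = "emgavatar_usage_error")
  }
  if (!all(is.finite(u))) {
    abort("Input series must be finite.", class = "emgavatar_usage_error")
  }
  st <- nmss_init(cascade)
  y <- numeric(length(u))
  for (k in seq_along(u)) {
    res <- nmss_step(st, u[k])
    st <- res$state
    y[k] <- res$y
  }
  y
}

#' Simulate an avatar trial
#'
#' Drives the NMSS cascade of a setting with an AA-ratio deviation series,
#' producing the angular displacement, the absolute elbow angle (standard
#' position 90 degrees plus displacement) and the angle resampled onto the
#' render-rate frame grid (linear interpolation, frames starting at t = 0;
#' a trial of duration `D` seconds yields `floor(D * render_rate)` frames).
#'
#' @param input Either a numeric vector of AA-ratio deviations sampled at
#'   `sim_rate`, or a data frame with a `delta_r` column (e.g. from
#'   [sigmoid_input()] or [compute_aa()]).
#' @param setting An [avatar_setting()] (or [nmss_params()]).
#' @param sim_rate Simulation rate in Hz, default 1000.
#' @param render_rate Frame rate in Hz, default 30.
#' @param standard_angle Absolute angle of the standard position in degrees,
#'   default 90.
#' @return An `avatar_trajectory` tibble with columns `time_s`, `delta_r`,
#'   `delta_theta_deg` and `angle_deg`, carrying the rendered frames
#'   (see [render_frames()]) and rates as attributes.
#' @examples
#' traj <- simulate_trial(sigmoid_input(duration = 1), standard_setting_of())
#' head(render_frames(traj))
#' @export
simulate_trial <- function(input, setting, sim_rate = 1000, render_rate = 30,
                           standard_angle = 90) {
  u <- if (is.data.frame(input)) {
    if (!"delta_r" %in% names(input)) {
      abort("`input` data frame must have a `delta_r` column.",
            class = "emgavatar_usage_error")
    }
    input$delta_r
  } else {
    as.numeric(input)
  }
  if (!length(u)) {
    abort("Input series is empty.", class = "emgavatar_usage_error")
  }
  if (inherits(setting, "nmss_params")) {
    setting <- avatar_setting("unnamed", setting)
  }
  stopifnot(inherits(setting, "avatar_setting"))
  casc <- build_cascade(setting$params, sim_rate)
  dtheta <- nmss_simulate(casc, u)
  n <- length(u)
  time_s <- (seq_len(n) - 1) / sim_rate
  angle <- standard_angle + dtheta
  duration <- n / sim_rate
  n_frames <- floor(duration * render_rate)
  frame_t <- (seq_len(n_frames) - 1) / render_rate
  frame_angle <- approx(time_s, angle, xout = frame_t, rule = 2)$y
  frames <- tibble(frame = seq_len(n_frames), time_s = frame_t,
                   angle_deg = frame_angle)
  out <- tibble(time_s = time_s, delta_r = u,
                delta_theta_deg = dtheta, angle_deg = angle)
  structure(out,
            class = c("avatar_trajectory", class(out)),
            frames = frames, sim_rate = sim_rate, render_rate = render_rate,
            setting = setting$name, standard_angle = standard_angle)
}

#' The shared standard setting
#'
#' Convenience accessor for the standard avatar setting (gain 300, natural
#' angular frequency 6 rad/s, damping 0.7, dead time 0).
#'
#' @return An [avatar_setting()].
#' @export
standard_setting_of <- function() standard_setting()

#' Rendered frames of a trajectory
#'
#' @param traj An `avatar_trajectory` from [simulate_trial()].
#' @return A tibble with columns `frame`, `time_s`, `angle_deg` at the
#'   render rate.
#' @export
render_frames <- function(traj) {
  stopifnot(inherits(traj, "avatar_trajectory"))
  attr(traj, "frames")
}

#' @export
autoplot.avatar_trajectory <- function(object, ...) {
  frames <- render_frames(object)
  ggplot(object, aes(x = .data$time_s, y = .data$angle_deg)) +
    geom_line(colour = "grey30") +
    geom_point(data = frames, colour = "steelblue", size = 0.6) +
    labs(x = "Time [s]", y = "Elbow angle [deg]",
         title = paste0("Avatar trajectory (", attr(object, "setting"), ")"),
         subtitle = "Line: simulation rate; points: rendered frames") +
    theme_minimal()
}
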