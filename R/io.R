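read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read and write EMG recordings as CSV
#'
#' The EMG schema is `time_s, emg_extensor, emg_flexor` with a header row;
#' the time base must be strictly increasing and uniform. Writing then
#' reading reproduces values to full double precision.
#'
#' @param path File path.
#' @return `read_emg_csv()`: a tibble in the EMG schema.
#' @export
read_emg_csv <- function(path) {
  data <- read_csv_quiet(path)
  check_emg_frame(data)
  infer_sample_rate(data$time_s)  # validates uniformity
  as_tibble(data)[c("time_s", "emg_extensor", "emg_flexor")]
}

#' @rdname read_emg_csv
#' @param data An EMG tibble.
#' @export
write_emg_csv <- function(data, path) {
  check_emg_frame(data)
  readr::write_csv(data, path)
  invisible(path)
}

#' Write a simulated trajectory as CSV
#'
#' At the simulation rate (`what = "sim"`) columns are
#' `time_s, delta_theta_deg, angle_deg`; at the render rate
#' (`what = "frames"`) columns are `frame, time_s, angle_deg`.
#'
#' @param traj An `avatar_trajectory` from [simulate_trial()].
#' @param path File path.
#' @param what `"sim"` or `"frames"`.
#' @export
write_trajectory_csv <- function(traj, path, what = c("sim", "frames")) {
  what <- match.arg(what)
  stopifnot(inherits(traj, "avatar_trajectory"))
  out <- if (what == "sim") {
    as_tibble(traj)[c("time_s", "delta_theta_deg", "angle_deg")]
  } else {
    render_frames(traj)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write questionnaire rating tables as CSV
#'
#' The canonical schema is `participant_id, experiment, setting,
#' repetition, soo, soa, cl`. Deposited tables in a different layout can be
#' adapted with `mapping`, a named character vector from canonical column
#' names to the names found in the file (e.g.
#' `c(participant_id = "Subject", soo = "ownership")`).
#'
#' Validation: every rating must lie in \[-3, 3\] and be an integer
#' multiple of 0.25 (the questionnaire's scale); violations are reported
#' with their row numbers.
#'
#' @param path File path.
#' @param mapping Optional named character vector renaming file columns to
#'   the canonical schema.
#' @return `read_ratings_csv()`: a ratings tibble in the canonical schema.
#' @export
read_ratings_csv <- function(path, mapping = NULL) {
  data <- read_csv_quiet(path)
  if (!is.null(mapping)) {
    missing_src <- setdiff(unname(mapping), names(data))
    if (length(missing_src)) {
      abort(paste0("Mapping refers to absent column(s): ",
                   paste(missing_src, collapse = ", ")),
            class = "emgavatar_format_error")
    }
    data <- rename(data, !!!setNames(unname(mapping), names(mapping)))
  }
  need <- c("participant_id", "setting", "repetition", rating_characteristics)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("Ratings CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "emgavatar_format_error")
  }
  if (!"experiment" %in% names(data)) data$experiment <- NA_character_
  for (col in rating_characteristics) {
    v <- data[[col]]
    bad <- which(is.na(v) | v < -3 | v > 3 | abs(v * 4 - round(v * 4)) > 1e-9)
    if (length(bad)) {
      abort(sprintf(
        "Column `%s`: invalid rating(s) at row(s) %s (must be in [-3, 3] in 0.25 steps).",
        col, paste(head(bad, 10), collapse = ", ")),
        class = "emgavatar_format_error")
    }
  }
  as_tibble(data)[c("participant_id", "experiment", "setting", "repetition",
                    rating_characteristics)]
}

#' @rdname read_ratings_csv
#' @param data A ratings tibble.
#' @export
write_ratings_csv <- function(data, path) {
  check_rating_table(data)
  readr::write_csv(data, path)
  invisible(path)
}

config_defaults <- function() {
  list(
    profile = "web5000",
    filters = list(hp_hz = 10, lp_hz = NULL, env_lp_hz = 22, order = 2,
                   causal = TRUE),
    mvc = list(method = "max"),
    aa = list(eps = 0.5, baseline_r = 0.5),
    sim_rate = 1000,
    render_rate = 30,
    catalog = "preliminary_omega",
    alpha = 0.05,
    seed = 1,
    out_dir = ".",
    log_level = "info"
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills in the study defaults (1000 Hz
#' simulation, 30 FPS rendering, 10 Hz/profile-dependent acquisition band,
#' 22 Hz envelope, alpha 0.05, standard catalog) and validates every field,
#' reporting all violations at once. The acquisition `profile` selects the
#' default low-pass cutoff: 100 Hz for `"web5000"`, 120 Hz for `"ebm102"`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated `run_config` list, including a resolved
#'   [filter_spec()] under `$filter_spec`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(paste0("Config file not found: ", path),
            class = "emgavatar_config_error")
    }
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(cfg))
      problems <- if (length(unknown)) {
        paste0("unknown key(s): ", paste(unknown, collapse = ", "))
      } else character()
      cfg <- modifyList(cfg, user[intersect(names(user), names(cfg))])
      if (length(problems)) {
        abort(paste0("Invalid configuration: ", paste(problems, collapse = "; ")),
              class = "emgavatar_config_error")
      }
    }
  }
  problems <- character()
  if (!cfg$profile %in% c("web5000", "ebm102")) {
    problems <- c(problems, "profile must be \"web5000\" or \"ebm102\"")
  }
  for (key in c("sim_rate", "render_rate")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      problems <- c(problems, paste0(key, " must be positive"))
    }
  }
  if (!is.numeric(cfg$aa$eps) || cfg$aa$eps <= 0) {
    problems <- c(problems, "aa.eps must be positive")
  }
  if (!is.numeric(cfg$aa$baseline_r) || cfg$aa$baseline_r < 0 ||
      cfg$aa$baseline_r > 1) {
    problems <- c(problems, "aa.baseline_r must lie in [0, 1]")
  }
  if (!cfg$mvc$method %in% c("max", "p95")) {
    problems <- c(problems, "mvc.method must be \"max\" or \"p95\"")
  }
  if (!cfg$catalog %in% c("preliminary_omega", "preliminary_deadtime",
                          "main_omega")) {
    problems <- c(problems, "catalog must name a built-in settings catalog")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    problems <- c(problems, "alpha must lie in (0, 1)")
  }
  if (length(problems)) {
    abort(paste0("Invalid configuration: ", paste(problems, collapse = "; ")),
          class = "emgavatar_config_error")
  }
  cfg$filter_spec <- filter_spec(
    hp_hz = cfg$filters$hp_hz,
    lp_hz = cfg$filters$lp_hz,
    env_lp_hz = cfg$filters$env_lp_hz,
    order = cfg$filters$order,
    causal = cfg$filters$causal,
    profile = cfg$profile
  )
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  profile: %s (band %g-%g Hz, envelope %g Hz)\n",
              x$profile, x$filter_spec$hp_hz, x$filter_spec$lp_hz,
              x$filter_spec$env_lp_hz))
  cat(sprintf("  sim %g Hz, render %g FPS, catalog %s, alpha %g, seed %d\n",
              x$sim_rate, x$render_rate, x$catalog, x$alpha, x$seed))
  invisible(x)
}

#' Read a settings catalog from YAML
#'
#' Expects a top-level `standard` block and a `comparisons` map of named
#' blocks, each with keys `K_NM, K_MS, omega_nNM, omega_nMS, zeta_NM,
#' zeta_MS, L_NM_ms, L_MS_ms` (missing keys default to the standard
#' setting's values).
#'
#' @param path YAML file path.
#' @param name Catalog name recorded on the result.
#' @return A `settings_catalog`.
#' @export
read_catalog_yaml <- function(path, name = "custom") {
  spec <- yaml::read_yaml(path)
  if (is.null(spec$standard) || is.null(spec$comparisons)) {
    abort("Catalog YAML needs `standard` and `comparisons` blocks.",
          class = "emgavatar_config_error")
  }
  block_to_params <- function(block, base = NULL) {
    get_val <- function(key, default) block[[key]] %||% default
    base <- base %||% list(K_NM = 300, K_MS = 1, omega_nNM = 6, omega_nMS = 6,
                           zeta_NM = 0.7, zeta_MS = 0.7, L_NM_ms = 0,
                           L_MS_ms = 0)
    filled <- lapply(setNames(names(base), names(base)),
                     function(k) get_val(k, base[[k]]))
    list(filled = filled,
         params = nmss_params(
           k_nm = filled$K_NM, k_ms = filled$K_MS,
           omega_nm = filled$omega_nNM, omega_ms = filled$omega_nMS,
           zeta_nm = filled$zeta_NM, zeta_ms = filled$zeta_MS,
           l_nm = filled$L_NM_ms / 1000, l_ms = filled$L_MS_ms / 1000))
  }
  std <- block_to_params(spec$standard)
  comparisons <- imap(spec$comparisons, function(block, nm) {
    avatar_setting(nm, block_to_params(block, std$filled)$params,
                   paste0("catalog ", name))
  })
  structure(list(standard = avatar_setting("standard", std$params,
                                           paste0("catalog ", name)),
                 comparisons = comparisons, name = name),
            class = "settings_catalog")
}
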