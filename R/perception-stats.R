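rating_characteristics <- c("soo", "soa", "cl")

check_rating_table <- function(data) {
  need <- c("participant_id", "setting", "repetition", rating_characteristics)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("Ratings table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "emgavatar_format_error")
  }
  vals <- unlist(data[rating_characteristics], use.names = FALSE)
  if (anyNA(vals)) {
    abort("Ratings table contains missing values; no imputation is performed.",
          class = "emgavatar_missing_data_error")
  }
  invisible(TRUE)
}

#' Per-participant rating means
#'
#' Averages the two repetitions of every setting within each participant
#' and characteristic -- the quantity all group-level statistics operate on.
#'
#' @param data A ratings tibble with columns `participant_id`, `setting`,
#'   `repetition` and the characteristics `soo`, `soa`, `cl` (as produced
#'   by [synth_ratings()] or [read_ratings_csv()]).
#' @return A long tibble with columns `participant_id`, `setting`,
#'   `characteristic`, `mean_rating`, `n_repetitions`.
#' @export
aggregate_ratings <- function(data) {
  check_rating_table(data)
  data |>
    as_tibble() |>
    pivot_longer(dplyr::all_of(rating_characteristics),
                 names_to = "characteristic", values_to = "value") |>
    group_by(.data$participant_id, .data$setting, .data$characteristic) |>
    summarise(mean_rating = mean(.data$value), n_repetitions = n(),
              .groups = "drop")
}

#' Across-participant rating summary
#'
#' The group-level view: mean and standard deviation of the per-participant
#' repetition means for every setting and characteristic.
#'
#' @inheritParams aggregate_ratings
#' @return A tibble with columns `setting`, `characteristic`, `mean`, `sd`,
#'   `n_participants`.
#' @export
setting_summary <- function(data) {
  aggregate_ratings(data) |>
    group_by(.data$setting, .data$characteristic) |>
    summarise(mean = mean(.data$mean_rating), sd = sd(.data$mean_rating),
              n_participants = n(), .groups = "drop")
}

#' Effect size from a t statistic
#'
#' \deqn{ES = \sqrt{t^2 / (t^2 + df)}}
#' Bounded in \[0, 1\], increasing in |t|, decreasing in df; independent of
#' sample-size-driven significance, which is why it accompanies every
#' pairwise comparison here.
#'
#' @param t_value t statistic (vectorized).
#' @param df Degrees of freedom; must be positive.
#' @return Effect size(s) in \[0, 1\].
#' @examples
#' effect_size(2.5, 5)
#' @export
effect_size <- function(t_value, df) {
  if (any(df <= 0)) {
    abort("`df` must be positive.", class = "emgavatar_parameter_error")
  }
  ifelse(is.infinite(t_value), 1, sqrt(t_value^2 / (t_value^2 + df)))
}

#' Categorize an effect size
#'
#' Category thresholds: `large` for ES >= 0.5 (starred `**`), `medium` for
#' ES >= 0.3 (starred `*`), `small` for ES >= 0.1, `slight` below 0.1.
#'
#' @param es Effect size(s) in \[0, 1\].
#' @return Character vector of categories.
#' @examples
#' classify_effect(c(0.05, 0.1, 0.3, 0.5))
#' @export
classify_effect <- function(es) {
  if (any(es < 0 | es > 1)) {
    abort("`es` must lie in [0, 1].", class = "emgavatar_parameter_error")
  }
  case_when(es >= 0.5 ~ "large",
            es >= 0.3 ~ "medium",
            es >= 0.1 ~ "small",
            TRUE ~ "slight")
}

#' @rdname classify_effect
#' @export
effect_stars <- function(es) {
  case_when(es >= 0.5 ~ "**", es >= 0.3 ~ "*", TRUE ~ "")
}

#' Format an effect size in leading-dot table style
#'
#' @param es Effect size(s).
#' @return Strings like `".13"`, two decimals without the leading zero.
#' @export
format_es <- function(es) {
  sub("^(-?)0\\.", "\\1.", sprintf("%.2f", es))
}

# one paired comparison on per-participant means; handles the degenerate
# zero-variance difference vector explicitly
paired_cell <- function(a, b) {
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      list(t = 0, df = n - 1, p = 1, degenerate = TRUE)
    } else {
      list(t = sign(mean(d)) * Inf, df = n - 1, p = 0, degenerate = TRUE)
    }
  } else {
    t <- mean(d) / (sd(d) / sqrt(n))
    df <- n - 1
    list(t = t, df = df, p = 2 * pt(-abs(t), df), degenerate = FALSE)
  }
}

#' Pairwise setting comparisons with Holm adjustment and effect sizes
#'
#' For one characteristic, compares every pair of settings by a paired
#' t-test on the per-participant repetition means, applies the
#' Holm-Bonferroni step-down adjustment across all pairs, and reports the
#' effect size [effect_size()] of each comparison with its category.
#'
#' The default test family is the paired t-test (df = n - 1). A
#' pooled-error variant (`method = "pooled"`) uses the participant-by-
#' setting interaction mean square of a two-way ANOVA as the common error
#' term (df = (n - 1)(k - 1)) for sensitivity analysis.
#'
#' A zero-variance difference vector is degenerate: the comparison is
#' flagged, with ES 1 if the mean difference is nonzero and ES 0 (p = 1)
#' if all differences are zero.
#'
#' @inheritParams aggregate_ratings
#' @param characteristic `"soo"`, `"soa"` or `"cl"`.
#' @param alpha Family-wise significance level, default 0.05.
#' @param settings Settings to include, in display order; default: every
#'   non-dummy setting in the table, in order of appearance.
#' @param method `"paired"` (default) or `"pooled"`.
#' @return A `perception_pairwise` object; [tidy()] returns the comparison
#'   table (`setting_a`, `setting_b`, `t`, `df`, `p_raw`, `p_holm`, `es`,
#'   `category`, `stars`, `significant`, `degenerate`), [glance()] a
#'   one-row summary.
#' @examples
#' plan <- make_protocol("main", nmss_catalog("main_omega"), seed = 2)
#' vp <- virtual_participants(6, settings = paste0("omega_nm", 1:6), seed = 2)
#' tab <- synth_ratings(vp, plan, seed = 2)
#' tidy(pairwise_compare(tab, "soo"))
#' @export
pairwise_compare <- function(data, characteristic = c("soo", "soa", "cl"),
                             alpha = 0.05, settings = NULL,
                             method = c("paired", "pooled")) {
  characteristic <- match.arg(characteristic)
  method <- match.arg(method)
  agg <- aggregate_ratings(data) |>
    filter(.data$characteristic == !!characteristic)
  if (is.null(settings)) {
    settings <- setdiff(unique(data$setting), "dummy")
  }
  agg <- agg |> filter(.data$setting %in% settings)
  wide <- agg |>
    select("participant_id", "setting", "mean_rating") |>
    pivot_wider(names_from = "setting", values_from = "mean_rating")
  if (anyNA(wide) || !all(settings %in% names(wide))) {
    abort("Every participant must have a rating for every included setting.",
          class = "emgavatar_missing_data_error")
  }
  n <- nrow(wide)
  if (n < 2) {
    abort("Need at least two participants.", class = "emgavatar_usage_error")
  }
  pairs <- utils::combn(settings, 2)
  cells <- map(seq_len(ncol(pairs)), function(j) {
    a <- wide[[pairs[1, j]]]
    b <- wide[[pairs[2, j]]]
    if (method == "paired") {
      paired_cell(a, b)
    } else {
      NULL  # filled below from the pooled error term
    }
  })
  if (method == "pooled") {
    long <- agg |> filter(.data$setting %in% settings)
    fit <- aov(mean_rating ~ factor(participant_id) + factor(setting),
               data = long)
    mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
    df_err <- summary(fit)[[1]]["Residuals", "Df"]
    cells <- map(seq_len(ncol(pairs)), function(j) {
      diff_mean <- mean(wide[[pairs[1, j]]]) - mean(wide[[pairs[2, j]]])
      t <- diff_mean / sqrt(2 * mse / n)
      list(t = t, df = df_err, p = 2 * pt(-abs(t), df_err), degenerate = FALSE)
    })
  }
  res <- tibble(
    setting_a = pairs[1, ],
    setting_b = pairs[2, ],
    t = map_dbl(cells, "t"),
    df = map_dbl(cells, "df"),
    p_raw = map_dbl(cells, "p"),
    degenerate = vapply(cells, `[[`, logical(1), "degenerate")
  ) |>
    mutate(
      p_holm = p.adjust(.data$p_raw, method = "holm"),
      es = effect_size(.data$t, .data$df),
      category = classify_effect(.data$es),
      stars = effect_stars(.data$es),
      significant = .data$p_holm < alpha
    ) |>
    select("setting_a", "setting_b", "t", "df", "p_raw", "p_holm",
           "es", "category", "stars", "significant", "degenerate")
  structure(
    list(results = res, characteristic = characteristic, alpha = alpha,
         method = method, n_participants = n, settings = settings),
    class = "perception_pairwise"
  )
}

#' @export
print.perception_pairwise <- function(x, ...) {
  cat(sprintf(
    "<perception_pairwise> %s, %d participants, %d pairs (%s t, Holm alpha = %g)\n",
    toupper(x$characteristic), x$n_participants, nrow(x$results), x$method,
    x$alpha))
  df <- x$results |>
    mutate(ES = paste0(format_es(.data$es), .data$stars)) |>
    select("setting_a", "setting_b", "t", "p_holm", "ES", "category")
  print(as.data.frame(df), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.perception_pairwise <- function(x, ...) {
  x$results
}

#' @export
glance.perception_pairwise <- function(x, ...) {
  tibble(
    characteristic = x$characteristic,
    n_participants = x$n_participants,
    n_pairs = nrow(x$results),
    n_significant = sum(x$results$significant),
    n_large = sum(x$results$category == "large"),
    alpha = x$alpha,
    method = x$method
  )
}

#' @export
autoplot.perception_pairwise <- function(object, ...) {
  df <- object$results |>
    mutate(setting_a = factor(.data$setting_a, levels = object$settings),
           setting_b = factor(.data$setting_b, levels = object$settings),
           label = paste0(format_es(.data$es), .data$stars))
  ggplot(df, aes(x = .data$setting_b, y = .data$setting_a, fill = .data$es)) +
    geom_tile() +
    geom_text(aes(label = .data$label), size = 3) +
    scale_fill_gradient2(low = "white", high = "firebrick", limits = c(0, 1),
                         name = "ES") +
    labs(x = NULL, y = NULL,
         title = paste0("Pairwise effect sizes (", toupper(object$characteristic), ")"),
         subtitle = "* medium (ES >= .3), ** large (ES >= .5)") +
    theme_minimal()
}

#' Distribution of peak-rated settings across participants
#'
#' For each participant, the setting(s) receiving the maximal
#' repetition-mean rating for a characteristic ("peak"); ties all count.
#' The histogram of peaks across participants probes how individual the
#' preferred dynamics are.
#'
#' @inheritParams pairwise_compare
#' @param settings Subset of settings (in display order) over which peaks
#'   are taken; default: every non-dummy setting in the table.
#' @return A `peak_histogram` tibble with columns `setting` and `count`;
#'   total count >= number of participants (ties add counts). The
#'   per-participant peak sets are kept in the `peaks` attribute.
#' @export
peak_distribution <- function(data, characteristic = c("soo", "soa", "cl"),
                              settings = NULL) {
  characteristic <- match.arg(characteristic)
  if (is.null(settings)) {
    settings <- setdiff(unique(data$setting), "dummy")
  }
  if (!length(settings)) {
    abort("`settings` must be non-empty.", class = "emgavatar_usage_error")
  }
  agg <- aggregate_ratings(data) |>
    filter(.data$characteristic == !!characteristic,
           .data$setting %in% settings)
  peaks <- agg |>
    group_by(.data$participant_id) |>
    filter(.data$mean_rating >= max(.data$mean_rating) - 1e-9) |>
    ungroup() |>
    select("participant_id", "setting")
  counts <- tibble(setting = settings) |>
    left_join(peaks |> group_by(.data$setting) |> summarise(count = n()),
              by = "setting") |>
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count))
  structure(counts, class = c("peak_histogram", class(counts)),
            characteristic = characteristic, peaks = peaks,
            n_participants = n_distinct(agg$participant_id))
}

#' @export
autoplot.peak_histogram <- function(object, ...) {
  df <- mutate(object, setting = factor(.data$setting, levels = object$setting))
  ggplot(df, aes(x = .data$setting, y = .data$count)) +
    geom_col(fill = "grey40") +
    labs(x = NULL, y = "Participants at peak",
         title = paste0("Peak distribution (",
                        toupper(attr(object, "characteristic")), ")"),
         subtitle = sprintf("%d participants; ties count for every tied setting",
                            attr(object, "n_participants"))) +
    theme_minimal()
}
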