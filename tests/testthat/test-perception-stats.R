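test_that("rating aggregation averages repetitions then participants", {
  tab <- ratings_from_means(list(A = c(1, 2), B = c(0, 0)))
  # two repetitions 1.0 and 2.0 for one participant -> mean 1.5
  tab$soo[tab$participant_id == 1 & tab$setting == "A"] <- c(1, 2)
  agg <- aggregate_ratings(tab)
  expect_equal(
    agg$mean_rating[agg$participant_id == 1 & agg$setting == "A" &
                      agg$characteristic == "soo"], 1.5)
  # identical participants -> zero SD
  same <- ratings_from_means(list(A = rep(1.25, 6), B = rep(-0.5, 6)))
  summ <- setting_summary(same)
  expect_true(all(summ$sd == 0))
  expect_equal(summ$mean[summ$setting == "A"], rep(1.25, 3))

  bad <- tab
  bad$soa[3] <- NA
  expect_error(aggregate_ratings(bad), class = "emgavatar_missing_data_error")
})

test_that("effect size follows sqrt(t^2 / (t^2 + df)) with its limiting behaviour", {
  expect_equal(effect_size(0, 5), 0)
  expect_equal(effect_size(sqrt(5), 5), sqrt(0.5))
  expect_equal(effect_size(-sqrt(5), 5), sqrt(0.5))
  # strictly increasing in |t|, strictly decreasing in df, bounded by 1
  ts <- seq(0, 50, by = 0.5)
  expect_true(all(diff(effect_size(ts, 5)) > 0))
  expect_true(all(diff(effect_size(2, 1:30)) < 0))
  expect_true(all(effect_size(ts, 5) < 1))
  expect_equal(effect_size(1e9, 5), 1, tolerance = 1e-6)
  expect_error(effect_size(1, 0), class = "emgavatar_parameter_error")
})

test_that("effect-size categories and stars follow the published thresholds", {
  expect_identical(classify_effect(c(0.5, 0.3, 0.1, 0.05, 0.99)),
                   c("large", "medium", "small", "slight", "large"))
  expect_identical(effect_stars(c(0.55, 0.35, 0.15, 0.05)),
                   c("**", "*", "", ""))
  expect_identical(format_es(c(0.13, 0.7)), c(".13", ".70"))
  expect_error(classify_effect(1.2), class = "emgavatar_parameter_error")
})

test_that("pairwise comparison matches the hand-computed paired-t oracle", {
  # participant means differ by (0.5, 0.5, 0.25, 0.75, 0.5, 0.5):
  # mean d = 0.5, var d = 0.025, so t = sqrt(n mean^2 / var) = sqrt(60),
  # df = 5, ES = sqrt(60 / 65)
  base <- c(0.5, -0.25, 0, 0.75, -0.5, 0.25)
  tab <- ratings_from_means(list(A = base + c(0.5, 0.5, 0.25, 0.75, 0.5, 0.5),
                                 B = base))
  res <- tidy(pairwise_compare(tab, "soo"))
  expect_equal(res$t, 7.745966692415, tolerance = 1e-10)
  expect_equal(res$df, 5)
  expect_equal(res$es, 0.960768922831, tolerance = 1e-10)
  expect_equal(res$p_raw, 0.000573245142, tolerance = 1e-8)
  expect_identical(res$category, "large")

  # identical vectors: t = 0, ES = 0, p = 1, flagged degenerate
  same <- ratings_from_means(list(A = base, B = base))
  res0 <- tidy(pairwise_compare(same, "cl"))
  expect_equal(res0$t, 0)
  expect_equal(res0$es, 0)
  expect_equal(res0$p_raw, 1)
  expect_true(res0$degenerate)

  # zero-variance nonzero difference: ES 1, p 0
  shifted <- ratings_from_means(list(A = base + 0.25, B = base))
  res1 <- tidy(pairwise_compare(shifted, "soa"))
  expect_equal(res1$es, 1)
  expect_equal(res1$p_raw, 0)
  expect_true(res1$degenerate)
})

test_that("Holm adjustment is monotone, dominates Bonferroni, and table shapes match the catalogs", {
  set.seed(123)
  settings4 <- paste0("s", 1:4)
  for (i in 1:10) {
    means <- lapply(settings4,
                    function(s) pmin(3, pmax(-3, round(rnorm(6) * 4) / 4)))
    names(means) <- settings4
    tab <- ratings_from_means(means)
    res <- tidy(pairwise_compare(tab, "soo"))
    expect_true(all(res$p_holm >= res$p_raw))
    ord <- order(res$p_raw)
    expect_true(all(diff(res$p_holm[ord]) >= -1e-12))
    # Holm rejects everything Bonferroni rejects at the same alpha
    bonf <- p.adjust(res$p_raw, "bonferroni") < 0.05
    expect_true(all(res$significant[bonf]))
  }

  plan_p <- make_protocol("preliminary", nmss_catalog("preliminary_omega"),
                          seed = 2)
  vp_p <- virtual_participants(6, settings = paste0("omega_np", 1:4), seed = 2)
  tab_p <- synth_ratings(vp_p, plan_p, seed = 2)
  expect_identical(nrow(tidy(pairwise_compare(tab_p, "soo"))), 6L)

  plan_m <- make_protocol("main", nmss_catalog("main_omega"), seed = 2)
  vp_m <- virtual_participants(6, settings = paste0("omega_nm", 1:6), seed = 2)
  tab_m <- synth_ratings(vp_m, plan_m, seed = 2)
  expect_identical(nrow(tidy(pairwise_compare(tab_m, "cl"))), 15L)

  # the pooled-error variant agrees on the direction of every comparison
  res_paired <- tidy(pairwise_compare(tab_m, "cl"))
  res_pooled <- tidy(pairwise_compare(tab_m, "cl", method = "pooled"))
  expect_equal(sign(res_pooled$t), sign(res_paired$t))
  expect_equal(res_pooled$df, rep(25, 15))
})

test_that("peak distribution counts argmax settings with ties counting everywhere", {
  tab <- ratings_from_means(list(A = c(2, 1, 1), B = c(2, 2, 0.5),
                                 C = c(1, 1, 0.5)))
  pk <- peak_distribution(tab, "soo")
  # participant 1 ties A/B, participant 2 peaks at B, participant 3 ties A and B? no:
  # p3: A=1, B=0.5, C=0.5 -> A only
  expect_equal(pk$count[pk$setting == "A"], 2L)
  expect_equal(pk$count[pk$setting == "B"], 2L)
  expect_equal(pk$count[pk$setting == "C"], 0L)
  expect_gte(sum(pk$count), 3)

  # zero-noise synthetic ratings put every participant exactly at the
  # argmax of their quantized true curve
  settings <- paste0("omega_nm", 1:6)
  plan <- make_protocol("main", nmss_catalog("main_omega"), seed = 5)
  vp0 <- virtual_participants(6, settings = settings, seed = 5, noise_sd = 0)
  tab0 <- synth_ratings(vp0, plan, seed = 5)
  for (chr in c("soo", "soa", "cl")) {
    pk0 <- peak_distribution(tab0, chr)
    found <- attr(pk0, "peaks") |> dplyr::arrange(participant_id, setting)
    truth <- participant_truth(vp0) |>
      dplyr::filter(characteristic == chr) |>
      dplyr::group_by(participant_id) |>
      dplyr::filter(scale_value >= max(scale_value) - 1e-9) |>
      dplyr::ungroup() |>
      dplyr::select(participant_id, setting) |>
      dplyr::arrange(participant_id, setting)
    expect_equal(as.data.frame(found), as.data.frame(truth))
  }

  expect_error(peak_distribution(tab, "soo", settings = character(0)),
               class = "emgavatar_usage_error")
})
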