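test_that("the sigmoid probe has its inflection at the centre with value one half", {
  sig <- sigmoid_input(duration = 1, sim_rate = 1e4)
  # logistic midpoint
  expect_equal(sig$delta_r[sig$time_s == 0.5], 0.5)
  # point symmetry about the centre: dr(t) + dr(2c - t) = 1
  t_probe <- seq(0.1, 0.9, by = 0.05)
  v <- function(tt) 1 / (1 + exp(20 / 3 * (tt - 0.5)))
  expect_equal(v(t_probe) + v(1 - t_probe), rep(1, length(t_probe)))
  expect_equal(sig$delta_r[match(round(t_probe, 6), round(sig$time_s, 6))] +
                 sig$delta_r[match(round(1 - t_probe, 6), round(sig$time_s, 6))],
               rep(1, length(t_probe)))
  # inflection on a 1e-4 s grid: steepest slope at 0.5 s
  fine <- sigmoid_input(duration = 1, sim_rate = 1e4)
  slope <- abs(diff(fine$delta_r))
  t_mid <- (fine$time_s[-1] + fine$time_s[-nrow(fine)]) / 2
  expect_equal(t_mid[which.max(slope)], 0.5, tolerance = 1e-3)
  # bounded and monotone decreasing
  expect_true(all(fine$delta_r > 0 & fine$delta_r < 1))
  expect_true(all(diff(fine$delta_r) < 0))
  expect_error(sigmoid_input(duration = 0), class = "emgavatar_usage_error")
})

test_that("synthetic EMG is seeded-deterministic and round-trips its envelope", {
  spec <- filter_spec()
  cal <- mvc_calibration(2, 3)
  prof <- activation_profile(2, m_e = 40, m_f = 15)
  a <- synth_emg(prof, cal, seed = 31, spec = spec)
  b <- synth_emg(prof, cal, seed = 31, spec = spec)
  expect_identical(a, b)
  c <- synth_emg(prof, cal, seed = 32, spec = spec)
  expect_false(identical(a$emg_extensor, c$emg_extensor))

  # zero envelope recovers zero activation
  silent <- synth_emg(activation_profile(1, m_e = 0, m_f = 0), cal, seed = 1,
                      spec = spec)
  act0 <- emg_activation(silent, spec, cal)
  expect_equal(act0$m_e, rep(0, nrow(act0)))

  # a slowly varying (sub-5 Hz) envelope is recovered within 10 % RMS,
  # comparing in the envelope's own band after aligning for the causal
  # chain's group delay
  prof_mod <- activation_profile(
    6, m_e = function(t) 35 + 15 * sin(2 * pi * 0.5 * t), m_f = 20)
  lp5 <- signal::butter(2, 5 / 500, "low")
  for (carrier in c("noise", "chirp")) {
    raw <- synth_emg(prof_mod, cal, seed = 33, spec = spec, carrier = carrier)
    act <- emg_activation(raw, spec, cal)
    rec <- as.numeric(signal::filtfilt(lp5, act$m_e))
    lag_n <- round(estimate_lag(prof_mod$m_e, rec, 1000, max_lag = 0.2) * 1000)
    keep <- which(act$time_s > 1 & act$time_s < 5.5)
    rms_err <- sqrt(mean((rec[keep] - prof_mod$m_e[keep - lag_n])^2))
    rms_ref <- sqrt(mean(prof_mod$m_e[keep]^2))
    expect_lt(rms_err / rms_ref, 0.10)
  }

  expect_error(synth_emg(prof[0, ], cal), class = "emgavatar_usage_error")
})

test_that("protocol plans satisfy the block structure and repetition counts", {
  main_cat <- nmss_catalog("main_omega")
  plan <- make_protocol("main", main_cat, seed = 4)
  comp <- plan[plan$role == "comparison" & !plan$is_dummy, ]
  expect_identical(nrow(comp), 12L)
  expect_true(all(table(comp$setting) == 2))
  # strict alternation: every phase is one standard exposure + one rated slot
  expect_true(all(table(plan$phase) == 2))
  expect_true(all(plan$role[plan$trial %% 2 == 1] == "standard"))

  pre <- make_protocol("preliminary", nmss_catalog("preliminary_omega"),
                       seed = 4)
  pre_comp <- pre[pre$role == "comparison", ]
  expect_true(all(table(pre_comp$setting[!pre_comp$is_dummy]) == 2))
  block_sizes <- as.integer(table(pre_comp$phase))
  expect_identical(block_sizes[-length(block_sizes)],
                   rep(3L, length(block_sizes) - 1))
  expect_identical(block_sizes[length(block_sizes)], 2L)
  # repetition indices count occurrences per setting
  expect_true(all(pre_comp$repetition[pre_comp$setting == "omega_np1"] %in% 1:2))

  # reproducibility
  expect_identical(make_protocol("main", main_cat, seed = 9),
                   make_protocol("main", main_cat, seed = 9))
  expect_false(identical(make_protocol("main", main_cat, seed = 9)$setting,
                         make_protocol("main", main_cat, seed = 10)$setting))

  expect_error(make_protocol("preliminary", tiny_catalog(1), seed = 1),
               class = "emgavatar_config_error")
})

test_that("synthetic ratings respect the questionnaire scale and encode the truth", {
  settings <- paste0("omega_np", 1:4)
  plan <- make_protocol("preliminary", nmss_catalog("preliminary_omega"),
                        seed = 8)
  vp <- virtual_participants(6, settings = settings, seed = 8, noise_sd = 0.4)
  tab <- synth_ratings(vp, plan, seed = 8)

  vals <- unlist(tab[c("soo", "soa", "cl")])
  expect_true(all(vals >= -3 & vals <= 3))
  expect_true(all(abs(vals * 4 - round(vals * 4)) < 1e-9))
  expect_identical(synth_ratings(vp, plan, seed = 8), tab)

  # noiseless raters report the quantized true curve; dummies rate 0
  vp0 <- virtual_participants(6, settings = settings, seed = 8, noise_sd = 0)
  tab0 <- synth_ratings(vp0, plan, seed = 8)
  truth <- participant_truth(vp0)
  joined <- dplyr::inner_join(
    tidyr::pivot_longer(tab0, c("soo", "soa", "cl"),
                        names_to = "characteristic", values_to = "value"),
    truth, by = c("participant_id", "characteristic", "setting"))
  expect_equal(joined$value, joined$scale_value)
  dummy_vals <- unlist(tab0[tab0$setting == "dummy", c("soo", "soa", "cl")])
  expect_true(all(dummy_vals == 0))

  # protocol count conservation flows into the table: 2 rows per setting
  non_dummy <- tab[tab$setting != "dummy", ]
  expect_true(all(table(non_dummy$setting, non_dummy$participant_id) == 2))
})
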