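test_that("acquisition band attenuates sub-band input and passes the band with known gain", {
  spec <- filter_spec()

  # silence in, silence out
  zero <- sine_recording(5, amplitude = 0)
  expect_equal(emg_bandpass_rectify(zero, spec)$emg_extensor,
               rep(0, nrow(zero)))

  # 5 Hz sits below the 10 Hz high-pass corner: rectified-mean amplitude
  # must match the designed magnitude response (and be well under 50 %)
  amp <- 2
  rec5 <- sine_recording(5, amplitude = amp)
  meas5 <- rectified_mean(emg_bandpass_rectify(rec5, spec)) * pi / 2
  gain5 <- band_gain_at(5, spec)
  expect_lt(meas5 / amp, 0.5)
  expect_equal(meas5 / amp, gain5, tolerance = 0.05)

  # 50 Hz is mid-band: rectified mean ~ 2A/pi times the near-unity gain
  rec50 <- sine_recording(50, amplitude = amp)
  mean50 <- rectified_mean(emg_bandpass_rectify(rec50, spec))
  expect_equal(mean50, 2 * amp * band_gain_at(50, spec) / pi,
               tolerance = 0.03)

  # cutoffs at or above Nyquist are rejected
  slow <- sine_recording(5, duration = 1, sample_rate = 180)
  expect_error(emg_bandpass_rectify(slow, spec),
               class = "emgavatar_config_error")
})

test_that("causal filtering is prefix-stable and zero-phase is selectable", {
  rec <- sine_recording(30, amplitude = 1, duration = 2)
  full <- emg_bandpass_rectify(rec, filter_spec(causal = TRUE))
  prefix <- emg_bandpass_rectify(rec[1:500, ], filter_spec(causal = TRUE))
  expect_equal(prefix$emg_extensor, full$emg_extensor[1:500])

  # zero-phase filtering is not prefix-stable (it looks ahead)
  full_zp <- emg_bandpass_rectify(rec, filter_spec(causal = FALSE))
  prefix_zp <- emg_bandpass_rectify(rec[1:500, ], filter_spec(causal = FALSE))
  expect_false(isTRUE(all.equal(prefix_zp$emg_extensor,
                                full_zp$emg_extensor[1:500])))
})

test_that("MVC self-calibration and envelope round trips recover commanded activations", {
  spec <- filter_spec()
  cal_unit <- mvc_calibration(1, 1)

  # zero raw input -> zero activation
  zero <- sine_recording(50, amplitude = 0, duration = 1)
  act0 <- emg_activation(zero, spec, cal_unit)
  expect_equal(act0$m_e, rep(0, nrow(act0)))
  expect_equal(act0$m_f, rep(0, nrow(act0)))

  # the MVC recording itself: peak activation ~100 %MVC by construction
  mvc_rec <- synth_emg(activation_profile(3, m_e = 100, m_f = 100),
                       cal_unit, seed = 11, spec = spec)
  cal <- mvc_from_recording(mvc_rec, spec)
  act_mvc <- emg_activation(mvc_rec, spec, cal)
  expect_gte(max(act_mvc$m_e), 90)
  expect_lte(max(act_mvc$m_e), 110)

  # constant half-MVC envelope -> steady-state activation 50 +- 5 %MVC
  half <- synth_emg(activation_profile(3, m_e = 50, m_f = 50),
                    cal_unit, seed = 12, spec = spec)
  act50 <- emg_activation(half, spec, cal_unit)
  steady <- act50[act50$time_s > 1, ]
  expect_equal(mean(steady$m_e), 50, tolerance = 0.1)
  expect_equal(mean(steady$m_f), 50, tolerance = 0.1)
  expect_true(all(act50$m_e >= 0) && all(act50$m_f >= 0))

  expect_error(mvc_calibration(0, 1), class = "emgavatar_calibration_error")
})

test_that("AA ratio obeys the defining arithmetic, the hold rule and conservation", {
  act <- tibble::tibble(m_e = c(20, 30, 0, 0, 10),
                        m_f = c(20, 10, 0, 0, 30))
  aa <- compute_aa(act, baseline_r = 0.5, eps = 0.5)
  expect_equal(aa$r[1], 0.5)
  expect_equal(aa$s[1], 40)
  expect_equal(aa$r[2], 0.75)
  expect_equal(aa$s[2], 40)
  # silent samples hold the last defined ratio
  expect_equal(aa$r[3:4], c(0.75, 0.75))
  expect_equal(aa$s[3:4], c(0, 0))
  expect_equal(aa$r[5], 0.25)
  expect_equal(aa$delta_r, aa$r - 0.5)

  # silence from the start holds the baseline
  rest <- compute_aa(tibble::tibble(m_e = c(0, 0), m_f = c(0, 0)),
                     baseline_r = 0.5)
  expect_equal(rest$r, c(0.5, 0.5))

  # conservation and range over a random activation table
  set.seed(7)
  tab <- tibble::tibble(m_e = runif(500, 0, 60), m_f = runif(500, 0, 60))
  aar <- compute_aa(tab, baseline_r = 0.4, eps = 0.5)
  live <- aar$s >= 0.5
  expect_equal(aar$r[live] * aar$s[live], aar$m_e[live])
  expect_equal((1 - aar$r[live]) * aar$s[live], aar$m_f[live])
  expect_true(all(aar$r >= 0 & aar$r <= 1))
  expect_true(all(aar$s >= 0))

  expect_error(compute_aa(tab, eps = 0), class = "emgavatar_config_error")
})

test_that("the AA ratio is invariant under common rescaling of channels and calibration", {
  spec <- filter_spec()
  prof <- activation_profile(2, m_e = function(t) 30 + 10 * sin(2 * pi * t),
                             m_f = 25)
  raw <- synth_emg(prof, mvc_calibration(1, 1), seed = 21, spec = spec)
  scale <- 7.3
  raw_scaled <- dplyr::mutate(raw,
                              emg_extensor = emg_extensor * scale,
                              emg_flexor = emg_flexor * scale)
  aa1 <- emg_activation(raw, spec, mvc_calibration(1, 1)) |> compute_aa()
  aa2 <- emg_activation(raw_scaled, spec,
                        mvc_calibration(scale, scale)) |> compute_aa()
  expect_equal(aa1$r, aa2$r, tolerance = 1e-10)
})

test_that("non-uniform or malformed time bases are rejected", {
  bad <- tibble::tibble(time_s = c(0, 0.001, 0.003),
                        emg_extensor = 0, emg_flexor = 0)
  expect_error(emg_bandpass_rectify(bad, filter_spec()),
               class = "emgavatar_format_error")
  expect_error(emg_bandpass_rectify(
    tibble::tibble(time_s = 1:3 / 1000, emg_extensor = 0),
    filter_spec()), class = "emgavatar_format_error")
})
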