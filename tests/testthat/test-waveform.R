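test_that("SPAD templates encode the configuration amplitude ordering", {
  expect_equal(single_spad_template("segmented")$amplitude, 26)
  expect_equal(single_spad_template("connected")$amplitude, 26 * 0.67)
  for (b in c(0.5, 1, 2)) {
    a <- vapply(c("nonsegmented", "connected", "segmented"), function(m)
      single_spad_template(m, bias_scale = b)$amplitude, numeric(1))
    expect_true(all(diff(a) > 0))
  }
  expect_equal(single_spad_template("segmented", bias_scale = 0)$amplitude, 0)
  expect_error(single_spad_template("bogus"), "arg")
  expect_error(pulse_template(10, 500, 300), "rise_tau < decay_tau")
  # rising edges slow down as capacitance grows
  expect_lt(single_spad_template("segmented")$rise_tau,
            single_spad_template("connected")$rise_tau)
  expect_lt(single_spad_template("connected")$rise_tau,
            single_spad_template("nonsegmented")$rise_tau)
})

test_that("pulse evaluation peaks at the template amplitude", {
  tpl <- single_spad_template()
  tt <- seq(-500, 10000, by = 1)
  v <- pulse_eval(tt, tpl)
  expect_equal(max(v), 26, tolerance = 1e-6)
  expect_true(all(v[tt <= 0] == 0))
  expect_true(all(v >= 0))
})

test_that("rendering is an exact superposition of template pulses", {
  tpl <- single_spad_template()
  z <- render_waveform(numeric(0), tpl, t0 = 0, n_samples = 50)
  expect_identical(z$samples, rep(0, 50))

  set.seed(11)
  arr <- sort(runif(30, 0, 15000))
  wf <- render_waveform(arr, tpl, t0 = -500, n_samples = 300, dt = 80)
  expect_equal(wf$samples, brute_waveform(arr, tpl, waveform_times(wf)),
               tolerance = 1e-9)

  # linearity: coincident arrivals double the trace
  one <- render_waveform(1000, tpl, t0 = 0, n_samples = 200)
  two <- render_waveform(c(1000, 1000), tpl, t0 = 0, n_samples = 200)
  expect_equal(two$samples, 2 * one$samples, tolerance = 1e-12)
  # peak equals the template peak within one-sample discretization
  expect_lte(max(one$samples), 26 + 1e-9)
  expect_gt(max(one$samples), pulse_eval(
    log(tpl$decay_tau / tpl$rise_tau) * tpl$rise_tau * tpl$decay_tau /
      (tpl$decay_tau - tpl$rise_tau) + 80, tpl))

  expect_error(render_waveform(1, tpl, 0, 10, noise_sigma = -1), ">= 0")
  n1 <- render_waveform(1, tpl, 0, 10, noise_sigma = 2, seed = 5)
  n2 <- render_waveform(1, tpl, 0, 10, noise_sigma = 2, seed = 5)
  expect_identical(n1$samples, n2$samples)
})

test_that("electronic crosstalk injects a threshold-limited bipolar pulse", {
  tpl <- single_spad_template()
  cfg <- crosstalk_config(electronic_amplitude_fraction = 0.5)
  a <- render_waveform(1000, tpl, t0 = 0, n_samples = 400)
  b <- render_waveform(numeric(0), tpl, t0 = 0, n_samples = 400)

  off <- inject_electronic_crosstalk(a, b, list(A = 1000, B = numeric(0)),
                                     crosstalk_config(0))
  expect_identical(off$B$samples, b$samples)

  on <- inject_electronic_crosstalk(a, b, list(A = 1000, B = numeric(0)), cfg)
  # opposite-polarity deflection in the quiet pixel
  expect_lt(min(on$B$samples), -1)
  # rebound peak is the configured fraction of the single-SPAD amplitude
  expect_equal(max(on$B$samples), 0.5 * 26, tolerance = 0.02)
  # leading-edge discrimination captures the crosstalk only below its
  # amplitude: raising the threshold above it removes the timestamp
  expect_false(is.na(leading_edge_timestamp(on$B, 10)))
  expect_true(is.na(leading_edge_timestamp(on$B, 0.5 * 26 * 1.1)))
  # aggressor trace is untouched
  expect_identical(on$A$samples, a$samples)

  bad <- render_waveform(numeric(0), tpl, t0 = 40, n_samples = 400)
  expect_error(inject_electronic_crosstalk(a, bad, list(A = 1, B = 1), cfg),
               "grid|share")
})

test_that("optical crosstalk spawns length-lagged secondaries", {
  arr_a <- data.frame(time_ps = rep(0, 4000), origin = "cherenkov")
  arr_b <- data.frame(time_ps = numeric(0), origin = character(0))
  off <- inject_optical_crosstalk(arr_a, arr_b, crosstalk_config(0), 10,
                                  seed = 1)
  expect_identical(nrow(off$arrivals_B), 0L)

  cfg <- crosstalk_config(optical_prob = 0.5, optical_delay_per_mm = 40)
  s10 <- inject_optical_crosstalk(arr_a, arr_b, cfg, 10, seed = 2)
  s20 <- inject_optical_crosstalk(arr_a, arr_b, cfg, 20, seed = 2)
  sec10 <- s10$arrivals_B
  sec20 <- s20$arrivals_B
  expect_true(all(sec10$origin == "optical_crosstalk"))
  # spawn probability
  expect_lt(abs(nrow(sec10) - 2000), 3 * sqrt(4000 * 0.25))
  # doubling the crystal length doubles the mean secondary lag
  expect_equal(mean(sec20$time_ps) / mean(sec10$time_ps), 2,
               tolerance = 0.05)
  expect_equal(mean(sec10$time_ps), 400, tolerance = 0.05)
})

test_that("the merged energy integral is linear in photon count", {
  tpl <- fast_template()
  n_samp <- 1500
  zero <- render_waveform(numeric(0), tpl, 0, n_samp, dt = 10)
  expect_identical(merged_energy_integral(zero, zero), 0)

  ref <- merged_energy_integral(
    render_waveform(500, tpl, 0, n_samp, dt = 10), zero)
  for (n in c(3, 17, 50)) {
    arr <- rep(500, n)
    to_a <- seq_len(n) %% 2 == 0
    wa <- render_waveform(arr[to_a], tpl, 0, n_samp, dt = 10)
    wb <- render_waveform(arr[!to_a], tpl, 0, n_samp, dt = 10)
    expect_equal(merged_energy_integral(wa, wb), n * ref,
                 tolerance = 1e-9)
  }
  # integrate-then-sum commutes with sum-then-integrate
  set.seed(3)
  arr <- runif(20, 0, 5000)
  whole <- merged_energy_integral(
    render_waveform(arr, tpl, 0, n_samp, dt = 10), zero)
  parts <- sum(vapply(arr, function(a) merged_energy_integral(
    render_waveform(a, tpl, 0, n_samp, dt = 10), zero), numeric(1)))
  expect_equal(whole, parts, tolerance = 1e-9)

  other <- render_waveform(numeric(0), tpl, 5, n_samp, dt = 10)
  expect_error(merged_energy_integral(zero, other), "grid|share")
})

test_that("waveform containers round-trip through the columnar layout", {
  tpl <- single_spad_template()
  wfs <- list(A = render_waveform(c(500, 900), tpl, 0, 120),
              B = render_waveform(700, tpl, 0, 120))
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveforms(wfs, path, event_id = 7L)
  back <- read_waveforms(path)
  expect_named(back, c("7.A", "7.B"))
  expect_equal(back[["7.A"]]$samples, wfs$A$samples)
  expect_equal(back[["7.B"]]$dt, 80)
})
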