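test_that("early integration captures exactly the windowed response", {
  tpl <- fast_template()
  wf <- render_waveform(500, tpl, t0 = 0, n_samples = 1500, dt = 10)
  full <- sum(pulse_eval(seq(0.5, 5000, by = 1), tpl))  # step-1 ps reference
  # single pulse fully inside the window: full reference charge
  q <- integrate_initial(wf, start = 450, window = 1000)
  expect_equal(q, full, tolerance = 0.01)
  # a pulse arriving after the window end contributes nothing
  expect_identical(integrate_initial(wf, start = 0, window = 400), 0)
  # pulse arriving late in the window is clipped by the window end
  late <- integrate_initial(wf, start = -300, window = 1000)
  expect_lt(late, q)
  expect_gt(late, 0)
  expect_true(is.na(integrate_initial(wf, NA_real_)))
  expect_error(integrate_initial(wf, 0, window = -5), "positive")
})

test_that("the single-photon grid pitch is recovered from charge spectra", {
  set.seed(41)
  u <- 10
  q <- rep(u * 1:3, each = 200) + rnorm(600, 0, 0.2)
  expect_equal(calibrate_single_photon_charge(q), u, tolerance = 0.02)
  expect_equal(calibrate_single_photon_charge(rep(7.3, 20)), 7.3)
  # 2% pitch recovery at 5% noise, 1e4 samples
  q2 <- u * sample(1:5, 1e4, replace = TRUE, prob = dpois(1:5, 2)) +
    rnorm(1e4, 0, 0.05 * u)
  expect_equal(calibrate_single_photon_charge(q2), u, tolerance = 0.02)
  expect_error(calibrate_single_photon_charge(numeric(0)), "at least one")
})

test_that("quantization rounds onto the charge grid", {
  expect_identical(quantize_photon_count(30, 10), 3L)
  expect_identical(quantize_photon_count(0, 10), 0L)
  expect_identical(quantize_photon_count(-4, 10), 0L)
  expect_identical(quantize_photon_count(NA_real_, 10), 0L)
  expect_identical(quantize_photon_count(c(9, 14, 26), 10), c(1L, 1L, 3L))
  expect_error(quantize_photon_count(5, 0), "positive")
})

test_that("quantized counts equal true arrival counts on clean events", {
  # prompt-only source, unit detection, no noise: the pipeline's quantized
  # counts must reproduce the per-pixel arrival counts exactly
  st <- simulate_coincidence_stream(prompt_cfg(), 150, reference_fwhm = 0,
                                    seed = 51)
  rec <- process_events(st, template = fast_template(), threshold = 3,
                        noise_sigma = 0, trace_start = -500,
                        trace_end = 4000, seed = 52)
  truth_a <- tabulate(factor(st$arrivals$event_id[st$arrivals$pixel == "A"],
                             levels = st$events$event_id), nbins = 150)
  truth_b <- tabulate(factor(st$arrivals$event_id[st$arrivals$pixel == "B"],
                             levels = st$events$event_id), nbins = 150)
  expect_identical(rec$n_A, as.integer(truth_a))
  expect_identical(rec$n_B, as.integer(truth_b))
  expect_identical(rec$n_total, as.integer(truth_a + truth_b))
})

test_that("the trigger time window zeroes only the delayed pixel", {
  # the documented example: pixel B 600 ps late with a 300 ps window
  z <- apply_trigger_time_window(3L, 4L, 1000, 1600, window = 300)
  expect_identical(z$n_A, 3L)
  expect_identical(z$n_B, 0L)
  expect_true(z$zeroed)
  # symmetric case
  z2 <- apply_trigger_time_window(3L, 4L, 1600, 1000, window = 300)
  expect_identical(z2$n_A, 0L)
  expect_identical(z2$n_B, 4L)
  # simultaneous triggers and the exact-boundary convention
  expect_identical(apply_trigger_time_window(2L, 5L, 100, 100)$n_B, 5L)
  expect_identical(apply_trigger_time_window(2L, 5L, 100, 400)$n_B, 5L)
  # a pixel that never triggered carries no initial photons
  z3 <- apply_trigger_time_window(2L, 5L, 100, NA)
  expect_identical(z3$n_B, 0L)
  expect_identical(z3$n_A, 2L)
  # idempotence
  z4 <- apply_trigger_time_window(z$n_A, z$n_B, 1000, 1600)
  expect_identical(z4$n_A, z$n_A)
  expect_identical(z4$n_B, z$n_B)
  expect_error(apply_trigger_time_window(1, 1, 0, 0, window = 0), "positive")
})

test_that("Poisson fitting recovers the mean and accepts Poisson data", {
  expect_equal(poisson_fit(rep(0L, 10))$mean, 0)
  expect_equal(poisson_fit(c(1L, 2L, 3L))$mean, 2)
  expect_error(poisson_fit(integer(0)), "non-empty")
  expect_error(poisson_fit(c(1.5, 2)), "integers")
  set.seed(61)
  x <- rpois(1e5, 5)
  fit <- poisson_fit(x)
  expect_lt(abs(fit$mean - 5), 3 * sqrt(5 / 1e5))
  expect_gt(fit$p_value, 0.01)
  # clearly non-Poisson data are rejected
  over <- rnbinom(1e5, mu = 5, size = 2)
  expect_lt(poisson_fit(over)$p_value, 1e-6)
})
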