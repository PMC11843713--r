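test_that("the energy window keeps photopeak events and drops the rest", {
  ev <- data.frame(energy_keV = c(511, 300, 450, 650, NA))
  kept <- energy_window_filter(ev, 400, 600)
  expect_identical(kept$energy_keV, c(511, 450))
  expect_error(energy_window_filter(ev, 600, 400), "lo < hi")
  expect_error(energy_window_filter(data.frame(x = 1), 400, 600), "lacks")

  # retained fraction on a continuum spectrum matches the analytic value:
  # the flat continuum ends below 400 keV, so only the photopeak survives
  cfg <- physics_config(energy_mode = "compton_continuum",
                        mean_scint_photons = 0, mean_cherenkov_photons = 0)
  st <- simulate_coincidence_stream(cfg, 2e4, seed = 91)
  ev2 <- data.frame(energy_keV = st$events$energy_keV)
  frac <- nrow(energy_window_filter(ev2, 400, 600)) / 2e4
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 2e4))
})

test_that("energy calibration anchors the photopeak at 511 keV", {
  expect_equal(calibrate_energy(rep(1000, 100)), 0.511)
  set.seed(93)
  c0 <- 5000
  q <- c(c0 * (1 + rnorm(6000, 0, 0.01)), runif(4000, 0.1 * c0, 0.66 * c0))
  expect_equal(calibrate_energy(q) * c0, 511, tolerance = 0.01)
  expect_error(calibrate_energy(numeric(0)), "too few")
})

test_that("the k sweep saturates to single-pixel timing at large |k|", {
  set.seed(97)
  n <- 4000
  ref <- rnorm(n, 0, 35)
  ev <- data.frame(
    T_A_ps = rnorm(n, 500, 90) + ref,
    T_B_ps = rnorm(n, 500, 90) + ref,
    reference_timestamp_ps = ref)
  span <- max(abs(ev$T_A_ps - ev$T_B_ps)) + 1
  vk <- ctr_vs_k(ev, k_grid = c(-span, 0, span), bin_width = 25)
  only_a <- fwhm_fwtm(build_histogram(ev$T_A_ps - ev$reference_timestamp_ps,
                                      25))
  only_b <- fwhm_fwtm(build_histogram(ev$T_B_ps - ev$reference_timestamp_ps,
                                      25))
  expect_equal(vk$fwhm_ps[vk$k_ps == span], only_a$fwhm)
  expect_equal(vk$fwhm_ps[vk$k_ps == -span], only_b$fwhm)
  # selecting the earlier timestamp cannot be worse than either pixel by
  # more than statistical jitter
  expect_lt(vk$fwhm_ps[vk$k_ps == 0],
            min(only_a$fwhm, only_b$fwhm) * 1.05)
  expect_error(ctr_vs_k(ev[, 1:2]), "lacks")
})

test_that("the widest selection window reproduces the unselected CTR", {
  set.seed(101)
  n <- 4000
  ref <- rnorm(n, 0, 35)
  ev <- data.frame(
    T_A_ps = rnorm(n, 500, 90) + ref,
    T_B_ps = rnorm(n, 500, 90) + ref,
    reference_timestamp_ps = ref)
  ev$delta_T_ps <- ev$T_A_ps - ev$T_B_ps
  top <- max(abs(ev$delta_T_ps)) + 1
  vd <- ctr_vs_dtk(ev, dtk_grid = c(200, top), bin_width = 25)
  all_h <- fwhm_fwtm(build_histogram(
    pmin(ev$T_A_ps, ev$T_B_ps) - ev$reference_timestamp_ps, 25))
  expect_equal(vd$fwhm_ps[2], all_h$fwhm)
  expect_identical(vd$n_selected[2], as.integer(n))
  expect_true(vd$n_selected[1] < vd$n_selected[2])
})

test_that("decile classes partition events into equal groups", {
  set.seed(103)
  n <- 1000
  ev <- data.frame(
    T_A_ps = rnorm(n, 500, 120),
    T_B_ps = rnorm(n, 500, 120),
    reference_timestamp_ps = rnorm(n, 0, 35))
  ev$delta_T_ps <- ev$T_A_ps - ev$T_B_ps
  kt <- classify_deciles(ev, bin_width = 50)
  expect_identical(kt$n_events, rep(100L, 10))
  expect_equal(sum(kt$event_fraction), 1)
  # one group reproduces the global CTR
  kt1 <- classify_deciles(ev, n_groups = 1, bin_width = 50)
  glob <- fwhm_fwtm(build_histogram(
    pmin(ev$T_A_ps, ev$T_B_ps) - ev$reference_timestamp_ps, 50))
  expect_equal(kt1$fwhm_ps, glob$fwhm)
  expect_error(classify_deciles(ev[1:5, ]), "at least")
})

test_that("photon-number kernels report one row per count", {
  ev <- data.frame(
    T_A_ps = rnorm(300, 0, 100), T_B_ps = rnorm(300, 0, 100),
    reference_timestamp_ps = 0, n_total = 3L)
  kt <- kernels_by_photon_number(ev, min_events = 100)
  expect_identical(nrow(kt), 1L)
  expect_identical(kt$class_id, 3L)
  expect_false(is.na(kt$fwhm_ps))
})

test_that("pairwise CTR algebra inverts the forward quadrature", {
  r <- solve_pair_resolutions(sqrt(2) * 100, sqrt(2) * 100, sqrt(2) * 100)
  expect_equal(unname(r), c(100, 100, 100), tolerance = 1e-12)
  set.seed(107)
  for (i in 1:50) {
    truth <- runif(3, 40, 300)
    ctr <- sqrt(c(truth[1]^2 + truth[2]^2, truth[1]^2 + truth[3]^2,
                  truth[2]^2 + truth[3]^2))
    got <- solve_pair_resolutions(ctr[1], ctr[2], ctr[3])
    expect_equal(unname(got), truth, tolerance = 1e-9)
    # round trip back to the pairwise measurements
    back <- sqrt(c(got[1]^2 + got[2]^2, got[1]^2 + got[3]^2,
                   got[2]^2 + got[3]^2))
    expect_equal(unname(back), ctr, tolerance = 1e-9)
  }
  expect_error(solve_pair_resolutions(1, 1, 10), "inconsistent")
  expect_equal(unname(subtract_reference(sqrt(100^2 + 83^2), 83)), 100,
               tolerance = 1e-12)
  expect_error(subtract_reference(50, 83), "below")
})

test_that("energy-binned summaries cover and partition the events", {
  set.seed(109)
  ev <- data.frame(
    energy_keV = runif(2000, 60, 590),
    delta_T_ps = rnorm(2000, 0, 400),
    n_total = rpois(2000, 3))
  out <- tdiff_by_energy(ev, energy_bins = seq(50, 600, by = 50))
  expect_identical(sum(out$summary$n_events), 2000L)
  # a single bin covering everything reproduces the global histogram
  single <- tdiff_by_energy(ev, energy_bins = c(50, 600))
  glob <- build_histogram(ev$delta_T_ps, 25)
  expect_identical(single$histograms[[1]]$counts, glob$counts)
  # an empty bin reports zero counts and NA mean
  gap <- tdiff_by_energy(ev[ev$energy_keV > 300, ],
                         energy_bins = c(50, 100, 600))
  expect_identical(gap$summary$n_events[1], 0L)
  expect_true(is.na(gap$summary$mean_n_total[1]))
  expect_error(tdiff_by_energy(ev, energy_bins = c(3, 2, 1)), "increasing")
})
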