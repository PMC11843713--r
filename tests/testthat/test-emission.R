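test_that("interaction sampling follows the energy-scaled Poisson means", {
  cfg <- physics_config()
  expect_error(simulate_interaction(cfg, 0), "positive")
  expect_error(simulate_interaction(cfg, -5), "positive")

  # Cherenkov population at 511 keV: mean 17 (scintillation silenced so the
  # draw loop stays cheap)
  cfg_ch <- physics_config(mean_scint_photons = 0)
  n_ch <- vapply(1:3000, function(i)
    simulate_interaction(cfg_ch, 511)$n_cherenkov, numeric(1))
  expect_lt(abs(mean(n_ch) - 17), 3 * sqrt(17 / 3000))

  # scintillation population at 511 keV: mean 4000, checked against the
  # analytic Poisson standard error
  set.seed(5)
  n_sc <- vapply(1:300, function(i)
    simulate_interaction(cfg, 511)$n_scint, numeric(1))
  expect_lt(abs(mean(n_sc) - 4000), 3 * sqrt(4000 / 300))

  # linear yield scaling with deposited energy
  cfg_half <- physics_config(mean_cherenkov_photons = 0,
                             mean_scint_photons = 400)
  n_half <- vapply(1:2000, function(i)
    simulate_interaction(cfg_half, 255.5)$n_scint, numeric(1))
  expect_lt(abs(mean(n_half) - 200), 3 * sqrt(200 / 2000))

  # below the Cherenkov threshold no Cherenkov photons are produced
  sub <- simulate_interaction(physics_config(mean_scint_photons = 0), 50,
                              seed = 1)
  expect_identical(sub$n_cherenkov, 0L)
})

test_that("emission times respect kinetics and the interaction time", {
  cfg <- physics_config(mean_scint_photons = 300, scint_decay_tau = 3000,
                        scint_rise_tau = 300)
  em <- simulate_interaction(cfg, 511, seed = 2, interaction_time = 1e4)
  expect_true(all(em$emissions$time_ps >= 1e4))
  ch <- em$emissions$time_ps[em$emissions$origin == "cherenkov"]
  expect_true(all(ch <= 1e4 + cfg$cherenkov_spread))
  # biexponential mean offset is rise_tau + decay_tau
  sc <- unlist(lapply(1:300, function(i) {
    e <- simulate_interaction(cfg, 511)$emissions
    e$time_ps[e$origin == "scintillation"]
  }))
  expect_lt(abs(mean(sc) - 3300), 3 * sqrt(3000^2 + 300^2) / sqrt(length(sc)))
})

test_that("transport thins binomially, splits pixels and delays arrivals", {
  emis <- data.frame(time_ps = rep(0, 1e5), origin = "scintillation")
  cfg <- physics_config(detection_prob = 0.25, loss_per_mm = 0,
                        crystal_length = 10)
  tr <- transport_photons(emis, cfg, seed = 3)
  n_det <- nrow(tr$arrivals_A) + nrow(tr$arrivals_B)
  expect_lt(abs(n_det - 2.5e4), 3 * sqrt(1e5 * 0.25 * 0.75))
  # split fraction
  expect_lt(abs(nrow(tr$arrivals_A) - n_det / 2), 3 * sqrt(n_det / 4))
  # arrivals acquire a non-negative transit delay with mean spread*length
  d <- c(tr$arrivals_A$time_ps, tr$arrivals_B$time_ps)
  expect_true(all(d >= 0))
  expect_lt(abs(mean(d) - 50), 3 * 50 / sqrt(n_det))

  expect_identical(
    nrow(transport_photons(emis[1:100, ],
                           physics_config(detection_prob = 0),
                           seed = 1)$arrivals_A), 0L)
  all_a <- transport_photons(emis[1:200, ],
                             physics_config(detection_prob = 1,
                                            loss_per_mm = 0,
                                            pixel_split_fraction = 1),
                             seed = 1)
  expect_identical(nrow(all_a$arrivals_B), 0L)
  expect_identical(nrow(all_a$arrivals_A), 200L)
})

test_that("detection probability falls with crystal length and black wrap", {
  p <- vapply(c(5, 10, 15, 20), function(L)
    effective_detection_prob(physics_config(crystal_length = L)), numeric(1))
  expect_true(all(diff(p) < 0))
  expect_lt(effective_detection_prob(physics_config(reflector_mode = "black")),
            effective_detection_prob(physics_config()))
  # black mode narrows the transit spread
  emis <- data.frame(time_ps = rep(0, 2e4), origin = "scintillation")
  d_w <- transport_photons(emis, physics_config(), seed = 4)
  d_b <- transport_photons(emis, physics_config(reflector_mode = "black"),
                           seed = 4)
  expect_lt(mean(c(d_b$arrivals_A$time_ps, d_b$arrivals_B$time_ps)),
            mean(c(d_w$arrivals_A$time_ps, d_w$arrivals_B$time_ps)))
})

test_that("coincidence streams are reproducible with reference jitter", {
  cfg <- quick_cfg()
  expect_error(simulate_coincidence_stream(cfg, -1), "non-negative")
  empty <- simulate_coincidence_stream(cfg, 0, seed = 1)
  expect_identical(nrow(empty$events), 0L)
  expect_identical(nrow(empty$arrivals), 0L)

  s1 <- simulate_coincidence_stream(cfg, 50, seed = 9)
  s2 <- simulate_coincidence_stream(cfg, 50, seed = 9)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$arrivals, s2$arrivals)

  jit_cfg <- physics_config(mean_cherenkov_photons = 0,
                            mean_scint_photons = 1, detection_prob = 0.1)
  st <- simulate_coincidence_stream(jit_cfg, 2e4, reference_fwhm = 83,
                                    seed = 10)
  jit <- st$events$reference_timestamp_ps - st$events$interaction_time_ps
  sigma <- 83 / (2 * sqrt(2 * log(2)))
  expect_lt(abs(sd(jit) - sigma), 3 * sigma / sqrt(2 * 2e4))
})

test_that("thinning-first and explicit transport samplers agree", {
  cfg <- physics_config(mean_cherenkov_photons = 10,
                        mean_scint_photons = 300, detection_prob = 0.3,
                        scint_decay_tau = 3000)
  fast <- simulate_coincidence_stream(cfg, 500, seed = 21, fast = TRUE)
  slow <- simulate_coincidence_stream(cfg, 500, seed = 22, fast = FALSE)
  m_f <- nrow(fast$arrivals) / 500
  m_s <- nrow(slow$arrivals) / 500
  lam <- (10 + 300) * effective_detection_prob(cfg)
  expect_lt(abs(m_f - m_s), 6 * sqrt(lam / 500) * sqrt(2))
  ks <- suppressWarnings(
    ks.test(fast$arrivals$time_ps, slow$arrivals$time_ps))
  expect_gt(ks$p.value, 0.001)
})

test_that("detected per-pixel counts stay Poisson under thinning", {
  cfg <- physics_config(mean_cherenkov_photons = 0,
                        mean_scint_photons = 60, detection_prob = 0.2)
  st <- simulate_coincidence_stream(cfg, 2e4, seed = 31)
  n_a <- tabulate(factor(st$arrivals$event_id[st$arrivals$pixel == "A"],
                         levels = st$events$event_id), nbins = 2e4)
  fit <- poisson_fit(n_a)
  lam <- 60 * effective_detection_prob(cfg) * 0.5
  expect_lt(abs(fit$mean - lam), 3 * sqrt(lam / 2e4))
  expect_gt(fit$p_value, 0.001)
})
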