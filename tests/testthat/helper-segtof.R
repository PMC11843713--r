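# shared fixtures: small, fast configurations used across the suite

# reduced-yield configuration for cheap unit tests (not the study conditions)
quick_cfg <- function(...) {
  args <- utils::modifyList(list(mean_scint_photons = 400,
                                 detection_prob = 0.3), list(...))
  do.call(physics_config, args)
}

# short pulse whose full response fits inside the 1 ns integration window
fast_template <- function(amplitude = 10) {
  pulse_template(amplitude = amplitude, rise_tau = 30, decay_tau = 120)
}

# prompt-only, noise-free, loss-free configuration for exact count oracles
prompt_cfg <- function(mean_photons = 5) {
  physics_config(mean_cherenkov_photons = mean_photons,
                 mean_scint_photons = 0,
                 detection_prob = 1, loss_per_mm = 0,
                 transit_spread_per_mm = 0.1, crystal_length = 5)
}

# small end-to-end pipeline run
quick_records <- function(n = 200, seed = 1, cfg = quick_cfg(), ...) {
  st <- simulate_coincidence_stream(cfg, n, seed = seed)
  process_events(st, seed = seed + 1L, ...)
}

# brute-force waveform evaluation used as rendering/timestamp oracle
brute_waveform <- function(arrivals, template, times) {
  vapply(times, function(t) sum(pulse_eval(t - arrivals, template)),
         numeric(1))
}

# study-condition simulation shared by the acceptance checks (built once)
.acc_cache <- new.env(parent = emptyenv())
acceptance_records <- function() {
  if (is.null(.acc_cache$records)) {
    st <- simulate_coincidence_stream(physics_config(), 20000, seed = 421)
    .acc_cache$records <- process_events(st, seed = 422)
  }
  .acc_cache$records
}
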