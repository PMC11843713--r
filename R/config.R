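#' Physics configuration for the coincidence simulator
#'
#' Bundles the emission, transport, and detection parameters of one simulated
#' BGO crystal coupled to two segmented SiPM pixels. All times are in
#' picoseconds, lengths in millimetres, energies in keV.
#'
#' @param mean_cherenkov_photons Mean number of Cherenkov photons produced by
#'   a full 511 keV energy deposition (default 17).
#' @param mean_scint_photons Mean number of scintillation photons at 511 keV
#'   (default 4000).
#' @param scint_decay_tau Scintillation decay time constant in ps
#'   (default 3e5, i.e. 300 ns).
#' @param scint_rise_tau Scintillation rise time constant in ps (default 300).
#' @param cherenkov_spread Width of the prompt Cherenkov emission burst in ps;
#'   emission offsets are uniform on `[0, cherenkov_spread]` (default 2).
#' @param light_yield_energy_scaling Rule tag for scintillation yield vs
#'   deposited energy; only `"linear"` is implemented.
#' @param cherenkov_energy_scaling Rule tag for Cherenkov yield vs deposited
#'   energy; `"linear"` scales the mean linearly above
#'   `cherenkov_energy_threshold`.
#' @param cherenkov_energy_threshold Energy (keV) below which no Cherenkov
#'   photons are produced (default 50); the recoil electron must exceed the
#'   Cherenkov threshold in the medium.
#' @param crystal_length Crystal length in mm; the measured configurations
#'   are 5, 10, 15 and 20 mm but any positive value is accepted (default 15).
#' @param transit_spread_per_mm Mean of the exponential transit-delay tail per
#'   mm of crystal, in ps/mm (default 5).
#' @param loss_per_mm Per-mm attenuation of the photon survival probability;
#'   the effective detection probability is
#'   `detection_prob * exp(-loss_per_mm * crystal_length)` (default 0.015).
#' @param detection_prob Photon detection probability at zero length
#'   (photodetection efficiency times transfer efficiency, default 0.2).
#' @param pixel_split_fraction Probability that a detected photon lands on
#'   pixel A rather than pixel B (default 0.5).
#' @param reflector_mode `"white"` (reflective wrap) or `"black"` (absorbing
#'   wrap). Black reduces survival by `black_survival_factor` and narrows the
#'   transit spread by `black_spread_factor` because reflected, long-path
#'   photons are absorbed.
#' @param black_survival_factor Extra survival multiplier in black mode
#'   (default 0.6).
#' @param black_spread_factor Transit-spread multiplier in black mode
#'   (default 0.3).
#' @param energy_mode `"photopeak_only"` (all events deposit 511 keV) or
#'   `"compton_continuum"` (a photopeak plus a flat continuum up to the
#'   Compton edge).
#' @param photopeak_fraction Fraction of photopeak events in
#'   `"compton_continuum"` mode (default 0.6).
#' @param compton_edge Upper end of the flat continuum in keV (default 340,
#'   the Compton edge for 511 keV).
#'
#' @return An object of class `physics_config` (a validated named list).
#' @examples
#' cfg <- physics_config(crystal_length = 20)
#' cfg$crystal_length
#' @export
physics_config <- function(mean_cherenkov_photons = 17,
                           mean_scint_photons = 4000,
                           scint_decay_tau = 3e5,
                           scint_rise_tau = 300,
                           cherenkov_spread = 2,
                           light_yield_energy_scaling = "linear",
                           cherenkov_energy_scaling = "linear",
                           cherenkov_energy_threshold = 50,
                           crystal_length = 15,
                           transit_spread_per_mm = 5,
                           loss_per_mm = 0.015,
                           detection_prob = 0.2,
                           pixel_split_fraction = 0.5,
                           reflector_mode = c("white", "black"),
                           black_survival_factor = 0.6,
                           black_spread_factor = 0.3,
                           energy_mode = c("photopeak_only", "compton_continuum"),
                           photopeak_fraction = 0.6,
                           compton_edge = 340) {
  cfg <- list(
    mean_cherenkov_photons = mean_cherenkov_photons,
    mean_scint_photons = mean_scint_photons,
    scint_decay_tau = scint_decay_tau,
    scint_rise_tau = scint_rise_tau,
    cherenkov_spread = cherenkov_spread,
    light_yield_energy_scaling = match.arg(light_yield_energy_scaling, "linear"),
    cherenkov_energy_scaling = match.arg(cherenkov_energy_scaling, "linear"),
    cherenkov_energy_threshold = cherenkov_energy_threshold,
    crystal_length = crystal_length,
    transit_spread_per_mm = transit_spread_per_mm,
    loss_per_mm = loss_per_mm,
    detection_prob = detection_prob,
    pixel_split_fraction = pixel_split_fraction,
    reflector_mode = match.arg(reflector_mode),
    black_survival_factor = black_survival_factor,
    black_spread_factor = black_spread_factor,
    energy_mode = match.arg(energy_mode),
    photopeak_fraction = photopeak_fraction,
    compton_edge = compton_edge
  )
  class(cfg) <- "physics_config"
  validate_physics_config(cfg)
}

validate_physics_config <- function(cfg) {
  stopifnot(inherits(cfg, "physics_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("mean_cherenkov_photons", "mean_scint_photons")) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("'%s' must be a non-negative number", f), call. = FALSE)
  }
  for (f in c("scint_decay_tau", "scint_rise_tau", "crystal_length")) {
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("'%s' must be a positive number", f), call. = FALSE)
  }
  for (f in c("cherenkov_spread", "transit_spread_per_mm", "loss_per_mm",
              "cherenkov_energy_threshold")) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("'%s' must be a non-negative number", f), call. = FALSE)
  }
  for (f in c("detection_prob", "pixel_split_fraction", "photopeak_fraction",
              "black_survival_factor", "black_spread_factor")) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", f), call. = FALSE)
  }
  if (cfg$scint_rise_tau >= cfg$scint_decay_tau)
    stop("'scint_rise_tau' must be smaller than 'scint_decay_tau'", call. = FALSE)
  if (!num1(cfg$compton_edge) || cfg$compton_edge <= 0 || cfg$compton_edge > 511)
    stop("'compton_edge' must lie in (0, 511] keV", call. = FALSE)
  cfg
}

#' @export
print.physics_config <- function(x, ...) {
  cat("<physics_config>\n")
  cat(sprintf("  emission : %g Cherenkov + %g scintillation photons @ 511 keV\n",
              x$mean_cherenkov_photons, x$mean_scint_photons))
  cat(sprintf("  kinetics : rise %g ps, decay %g ps, Cherenkov spread %g ps\n",
              x$scint_rise_tau, x$scint_decay_tau, x$cherenkov_spread))
  cat(sprintf("  crystal  : %g mm, %s reflector, loss %g /mm, transit %g ps/mm\n",
              x$crystal_length, x$reflector_mode, x$loss_per_mm,
              x$transit_spread_per_mm))
  cat(sprintf("  detection: p = %g (effective %.4f), split A = %g\n",
              x$detection_prob, effective_detection_prob(x),
              x$pixel_split_fraction))
  cat(sprintf("  spectrum : %s\n", x$energy_mode))
  invisible(x)
}

#' Effective per-photon detection probability of a configuration
#'
#' Combines the base detection probability, the exponential length-dependent
#' transport loss, and the black-reflector penalty.
#'
#' @param config A [physics_config()].
#' @return A single probability.
#' @export
effective_detection_prob <- function(config) {
  validate_physics_config(config)
  p <- config$detection_prob * exp(-config$loss_per_mm * config$crystal_length)
  if (config$reflector_mode == "black") p <- p * config$black_survival_factor
  p
}

#' Crosstalk configuration
#'
#' Parameters of the two crosstalk mechanisms between the segmented pixels:
#' electronic crosstalk (a bipolar, threshold-sensitive deflection induced in
#' the quiet pixel when the other pixel fires, length-independent) and
#' optical crosstalk (secondary photon arrivals in the opposite pixel with a
#' crystal-length-dependent lag).
#'
#' @param electronic_amplitude_fraction Rebound amplitude of the induced
#'   electronic-crosstalk pulse, as a fraction of the single-SPAD amplitude
#'   (default 0.6); 0 disables electronic crosstalk.
#' @param electronic_delay Delay (ps) between the aggressor onset and the
#'   injected crosstalk pulse (default 800).
#' @param rebound_lag Lag (ps) between the negative lobe and the recovery
#'   rebound of the bipolar crosstalk shape (default 300).
#' @param optical_prob Probability that a detected photon spawns a secondary
#'   arrival in the opposite pixel (default 0); 0 disables optical crosstalk.
#' @param optical_delay_per_mm Mean secondary lag per mm of crystal length,
#'   ps/mm (default 40).
#' @param optical_jitter_frac Relative Gaussian jitter on the secondary lag
#'   (default 0.15).
#'
#' @return An object of class `crosstalk_config`.
#' @export
crosstalk_config <- function(electronic_amplitude_fraction = 0.6,
                             electronic_delay = 800,
                             rebound_lag = 300,
                             optical_prob = 0,
                             optical_delay_per_mm = 40,
                             optical_jitter_frac = 0.15) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(electronic_amplitude_fraction) ||
      electronic_amplitude_fraction < 0 || electronic_amplitude_fraction > 1)
    stop("'electronic_amplitude_fraction' must be in [0, 1]", call. = FALSE)
  if (!num1(optical_prob) || optical_prob < 0 || optical_prob > 1)
    stop("'optical_prob' must be in [0, 1]", call. = FALSE)
  if (!num1(electronic_delay) || electronic_delay < 0)
    stop("'electronic_delay' must be >= 0", call. = FALSE)
  if (!num1(rebound_lag) || rebound_lag <= 0)
    stop("'rebound_lag' must be > 0", call. = FALSE)
  if (!num1(optical_delay_per_mm) || optical_delay_per_mm < 0)
    stop("'optical_delay_per_mm' must be >= 0", call. = FALSE)
  if (!num1(optical_jitter_frac) || optical_jitter_frac < 0)
    stop("'optical_jitter_frac' must be >= 0", call. = FALSE)
  structure(list(
    electronic_amplitude_fraction = electronic_amplitude_fraction,
    electronic_delay = electronic_delay,
    rebound_lag = rebound_lag,
    optical_prob = optical_prob,
    optical_delay_per_mm = optical_delay_per_mm,
    optical_jitter_frac = optical_jitter_frac
  ), class = "crosstalk_config")
}

#' @export
print.crosstalk_config <- function(x, ...) {
  cat("<crosstalk_config>\n")
  cat(sprintf("  electronic: fraction %g, delay %g ps, rebound lag %g ps\n",
              x$electronic_amplitude_fraction, x$electronic_delay, x$rebound_lag))
  cat(sprintf("  optical   : prob %g, %g ps/mm (jitter %g)\n",
              x$optical_prob, x$optical_delay_per_mm, x$optical_jitter_frac))
  invisible(x)
}

#' Analysis configuration
#'
#' Parameters of the timing analysis stage.
#'
#' @param energy_window Two keV values, lower then upper, of the event energy
#'   selection (default `c(400, 600)`).
#' @param bin_width Histogram bin width in ps (default 25).
#' @param delta_T_k Trigger-time-difference selection half-window in ps
#'   (default 300).
#' @param fwhm_method `"gauss_fit"` (Gaussian fit to the peak core for FWHM,
#'   direct 10%-height interpolation for FWTM) or `"direct"` (both widths
#'   interpolated from the binned histogram).
#' @param reference_fwhm Timing resolution of the reference detector in ps
#'   (default 83); kept with the results for optional quadrature subtraction.
#'
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(energy_window = c(400, 600),
                            bin_width = 25,
                            delta_T_k = 300,
                            fwhm_method = c("gauss_fit", "direct"),
                            reference_fwhm = 83) {
  if (!is.numeric(energy_window) || length(energy_window) != 2L ||
      energy_window[1] >= energy_window[2])
    stop("'energy_window' must be c(lo, hi) with lo < hi", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a positive number", call. = FALSE)
  if (!is.numeric(delta_T_k) || length(delta_T_k) != 1L || delta_T_k <= 0)
    stop("'delta_T_k' must be a positive number", call. = FALSE)
  if (!is.numeric(reference_fwhm) || length(reference_fwhm) != 1L ||
      reference_fwhm < 0)
    stop("'reference_fwhm' must be >= 0", call. = FALSE)
  structure(list(
    energy_window = as.numeric(energy_window),
    bin_width = bin_width,
    delta_T_k = delta_T_k,
    fwhm_method = match.arg(fwhm_method),
    reference_fwhm = reference_fwhm
  ), class = "analysis_config")
}

#' Read or write a configuration file
#'
#' Configurations are stored as plain JSON or YAML documents whose keys match
#' the [physics_config()] arguments (times in ps, lengths in mm, energies in
#' keV). The format is chosen from the file extension (`.json`, `.yaml`,
#' `.yml`).
#'
#' @param path File path.
#' @return `read_physics_config()` returns a validated [physics_config()];
#'   `write_physics_config()` returns `path` invisibly.
#' @export
read_physics_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(physics_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(physics_config, vals)
}

#' @rdname read_physics_config
#' @param config A [physics_config()].
#' @export
write_physics_config <- function(config, path) {
  validate_physics_config(config)
  vals <- unclass(config)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

# seeded evaluation without touching the caller's RNG stream when seed is NULL
with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
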