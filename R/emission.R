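#' Simulate photon emission for one annihilation-photon interaction
#'
#' Draws the Cherenkov and scintillation photon numbers for a single energy
#' deposition and their emission times. Cherenkov photons are prompt
#' (uniform within `cherenkov_spread` of the interaction); scintillation
#' emission times follow the rise/decay biexponential, sampled as the sum of
#' an exponential rise and an exponential decay delay.
#'
#' Yields scale with deposited energy: the scintillation mean linearly from
#' `mean_scint_photons` at 511 keV, the Cherenkov mean linearly above the
#' Cherenkov threshold (`cherenkov_energy_threshold`), reaching
#' `mean_cherenkov_photons` at 511 keV.
#'
#' @param config A [physics_config()].
#' @param energy Deposited energy in keV (> 0).
#' @param seed Optional integer seed; the caller's RNG state is untouched
#'   when a seed is given.
#' @param interaction_time Interaction time in ps (default 0); emission times
#'   are absolute.
#'
#' @return A list with `n_cherenkov`, `n_scint`, and an `emissions`
#'   data.frame with columns `time_ps` and `origin`
#'   (`"cherenkov"`/`"scintillation"`).
#' @examples
#' em <- simulate_interaction(physics_config(), 511, seed = 1)
#' em$n_cherenkov
#' @export
simulate_interaction <- function(config, energy, seed = NULL,
                                 interaction_time = 0) {
  validate_physics_config(config)
  if (!is.numeric(energy) || length(energy) != 1L || !is.finite(energy) ||
      energy <= 0)
    stop("'energy' must be a positive number of keV", call. = FALSE)
  with_seed(seed, {
    mu <- emission_means(config, energy)
    n_ch <- stats::rpois(1L, mu$cherenkov)
    n_sc <- stats::rpois(1L, mu$scint)
    t_ch <- interaction_time + stats::runif(n_ch, 0, config$cherenkov_spread)
    t_sc <- interaction_time + sample_scint_times(n_sc, config)
    list(
      n_cherenkov = n_ch,
      n_scint = n_sc,
      emissions = data.frame(
        time_ps = c(t_ch, t_sc),
        origin = rep(c("cherenkov", "scintillation"), c(n_ch, n_sc)),
        stringsAsFactors = FALSE
      )
    )
  })
}

# Poisson means for both populations at a given deposited energy (vectorized)
emission_means <- function(config, energy) {
  scint <- config$mean_scint_photons * energy / 511
  thr <- config$cherenkov_energy_threshold
  cher <- config$mean_cherenkov_photons *
    pmax(0, energy - thr) / (511 - thr)
  list(cherenkov = cher, scint = scint)
}

# biexponential emission-time sampler: rise + decay hypoexponential, whose
# density is proportional to exp(-t/tau_d) - exp(-t/tau_r)
sample_scint_times <- function(n, config) {
  if (n == 0L) return(numeric(0))
  stats::rexp(n, rate = 1 / config$scint_rise_tau) +
    stats::rexp(n, rate = 1 / config$scint_decay_tau)
}

#' Transport emitted photons to the two segmented pixels
#'
#' Each emitted photon independently survives transport and detection with
#' the configuration's effective detection probability (base probability,
#' exponential per-mm loss, and the black-reflector penalty). Survivors are
#' assigned to pixel A with probability `pixel_split_fraction`, otherwise to
#' pixel B, and acquire an exponential transit delay with mean
#' `transit_spread_per_mm * crystal_length` (narrowed by
#' `black_spread_factor` in black mode).
#'
#' @param emissions A data.frame with columns `time_ps` and `origin`, as
#'   produced by [simulate_interaction()].
#' @param config A [physics_config()].
#' @param seed Optional integer seed.
#'
#' @return A list with data.frames `arrivals_A` and `arrivals_B`, each with
#'   columns `time_ps` and `origin`.
#' @export
transport_photons <- function(emissions, config, seed = NULL) {
  validate_physics_config(config)
  stopifnot(is.data.frame(emissions),
            all(c("time_ps", "origin") %in% names(emissions)))
  with_seed(seed, {
    n <- nrow(emissions)
    p <- effective_detection_prob(config)
    keep <- stats::runif(n) < p
    det <- emissions[keep, , drop = FALSE]
    m <- nrow(det)
    delay <- stats::rexp(m, rate = 1 / transit_spread(config))
    time <- det$time_ps + delay
    to_a <- stats::runif(m) < config$pixel_split_fraction
    list(
      arrivals_A = data.frame(time_ps = time[to_a], origin = det$origin[to_a],
                              stringsAsFactors = FALSE),
      arrivals_B = data.frame(time_ps = time[!to_a], origin = det$origin[!to_a],
                              stringsAsFactors = FALSE)
    )
  })
}

transit_spread <- function(config) {
  s <- config$transit_spread_per_mm * config$crystal_length
  if (config$reflector_mode == "black") s <- s * config$black_spread_factor
  max(s, 1e-9)
}

#' Simulate a stream of coincidence events
#'
#' Generates `n_events` annihilation coincidences: per-event deposited
#' energy (photopeak-only or photopeak + flat Compton continuum), detected
#' photon arrivals at the two segmented pixels, and a reference-detector
#' timestamp carrying Gaussian jitter with the configured FWHM.
#'
#' By default the generator uses a thinning-first fast path: the number of
#' detected photons per pixel is drawn directly from the thinned Poisson law
#' and emission plus transit times are sampled only for detected photons.
#' This is statistically identical to emitting every photon and transporting
#' it (`fast = FALSE`), because survival marks are independent of emission
#' times; the slow path is retained for cross-validation.
#'
#' @param config A [physics_config()].
#' @param n_events Number of coincidences (>= 0).
#' @param reference_fwhm Reference-detector timing resolution in ps, applied
#'   as Gaussian jitter on the reference timestamp (default 83).
#' @param seed Optional integer seed; a fixed seed makes the stream
#'   reproducible.
#' @param interaction_time Common interaction time in ps (default 0).
#' @param fast Use the thinning-first sampler (default `TRUE`).
#' @param max_time Optional cutoff in ps: arrivals later than this are
#'   dropped at generation (default `Inf`, keep everything). Later arrivals
#'   cannot influence timestamps taken on a trace that ends before the
#'   cutoff, so timing studies can cap memory this way; full-stream charge
#'   integrals, however, do depend on the dropped tail.
#'
#' @return An object of class `coincidence_stream`: a list with
#'   \describe{
#'     \item{events}{data.frame `event_id`, `energy_keV`,
#'       `interaction_time_ps`, `reference_timestamp_ps`}
#'     \item{arrivals}{data.frame `event_id`, `pixel` (`"A"`/`"B"`),
#'       `time_ps`, `origin`}
#'     \item{config}{the generating configuration}
#'   }
#' @examples
#' st <- simulate_coincidence_stream(physics_config(), 10, seed = 7)
#' nrow(st$events)
#' @export
simulate_coincidence_stream <- function(config, n_events, reference_fwhm = 83,
                                        seed = NULL, interaction_time = 0,
                                        fast = TRUE, max_time = Inf) {
  validate_physics_config(config)
  if (!is.numeric(n_events) || length(n_events) != 1L || n_events < 0 ||
      n_events != round(n_events))
    stop("'n_events' must be a non-negative integer", call. = FALSE)
  if (reference_fwhm < 0)
    stop("'reference_fwhm' must be >= 0", call. = FALSE)
  n_events <- as.integer(n_events)
  with_seed(seed, {
    energy <- sample_energies(config, n_events)
    ref_sigma <- reference_fwhm / FWHM_SIGMA
    ref <- interaction_time +
      if (ref_sigma > 0) stats::rnorm(n_events, 0, ref_sigma) else
        numeric(n_events)
    events <- data.frame(
      event_id = seq_len(n_events),
      energy_keV = energy,
      interaction_time_ps = rep(interaction_time, n_events),
      reference_timestamp_ps = ref
    )
    arrivals <- if (fast) {
      sample_arrivals_fast(config, events, max_time)
    } else {
      sample_arrivals_explicit(config, events, max_time)
    }
    structure(list(events = events, arrivals = arrivals, config = config),
              class = "coincidence_stream")
  })
}

# conversion between a Gaussian sigma and its full width at half maximum
FWHM_SIGMA <- 2 * sqrt(2 * log(2))

sample_energies <- function(config, n) {
  if (config$energy_mode == "photopeak_only") return(rep(511, n))
  peak <- stats::runif(n) < config$photopeak_fraction
  e <- numeric(n)
  e[peak] <- 511
  e[!peak] <- stats::runif(sum(!peak), 50, config$compton_edge)
  e
}

# thinning-first sampler: detected counts per pixel/origin are Poisson with
# mean lambda * p_detect * split; times are drawn i.i.d. for survivors only
sample_arrivals_fast <- function(config, events, max_time = Inf) {
  n <- nrow(events)
  if (n == 0L) return(empty_arrivals())
  mu <- emission_means(config, events$energy_keV)
  p <- effective_detection_prob(config)
  split <- config$pixel_split_fraction
  counts <- list(
    A_ch = stats::rpois(n, mu$cherenkov * p * split),
    B_ch = stats::rpois(n, mu$cherenkov * p * (1 - split)),
    A_sc = stats::rpois(n, mu$scint * p * split),
    B_sc = stats::rpois(n, mu$scint * p * (1 - split))
  )
  blocks <- Map(function(cnt, pixel, origin) {
    total <- sum(cnt)
    if (total == 0L) return(empty_arrivals())
    t0 <- rep(events$interaction_time_ps, cnt)
    emit <- if (origin == "cherenkov") {
      stats::runif(total, 0, config$cherenkov_spread)
    } else {
      sample_scint_times(total, config)
    }
    delay <- stats::rexp(total, rate = 1 / transit_spread(config))
    time <- t0 + emit + delay
    keep <- time <= max_time
    data.frame(event_id = rep(events$event_id, cnt)[keep], pixel = pixel,
               time_ps = time[keep], origin = origin,
               stringsAsFactors = FALSE)
  },
  counts, c("A", "B", "A", "B"),
  c("cherenkov", "cherenkov", "scintillation", "scintillation"))
  arr <- do.call(rbind, blocks)
  arr <- arr[order(arr$event_id, arr$pixel, arr$time_ps), , drop = FALSE]
  rownames(arr) <- NULL
  arr
}

# explicit emit-then-transport sampler (slow; used for cross-validation)
sample_arrivals_explicit <- function(config, events, max_time = Inf) {
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    em <- simulate_interaction(config, events$energy_keV[i],
                               interaction_time = events$interaction_time_ps[i])
    tr <- transport_photons(em$emissions, config)
    a <- tr$arrivals_A[tr$arrivals_A$time_ps <= max_time, , drop = FALSE]
    b <- tr$arrivals_B[tr$arrivals_B$time_ps <= max_time, , drop = FALSE]
    out[[i]] <- data.frame(
      event_id = events$event_id[i],
      pixel = rep(c("A", "B"), c(nrow(a), nrow(b))),
      time_ps = c(a$time_ps, b$time_ps),
      origin = c(a$origin, b$origin),
      stringsAsFactors = FALSE
    )
  }
  arr <- do.call(rbind, c(out, list(empty_arrivals())))
  arr <- arr[order(arr$event_id, arr$pixel, arr$time_ps), , drop = FALSE]
  rownames(arr) <- NULL
  arr
}

empty_arrivals <- function() {
  data.frame(event_id = integer(0), pixel = character(0),
             time_ps = numeric(0), origin = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.coincidence_stream <- function(x, ...) {
  cat(sprintf("<coincidence_stream> %d events, %d detected photon arrivals\n",
              nrow(x$events), nrow(x$arrivals)))
  cat(sprintf("  crystal %g mm (%s), %s\n", x$config$crystal_length,
              x$config$reflector_mode, x$config$energy_mode))
  invisible(x)
}
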