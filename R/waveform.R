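#' Uniformly sampled waveform
#'
#' A voltage trace on a uniform time grid: sample `i` is the voltage at
#' `t0 + (i - 1) * dt`. The default 80 ps sampling step corresponds to the
#' 12.5 GS/s digitizer rate.
#'
#' @param samples Numeric vector of voltages, mV.
#' @param t0 Time of the first sample, ps.
#' @param dt Sampling step, ps (> 0).
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, t0 = 0, dt = 80) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a positive sampling step in ps", call. = FALSE)
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples)))
    stop("'samples' must be finite numeric voltages", call. = FALSE)
  structure(list(t0 = t0, dt = dt, samples = as.numeric(samples)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g ps (t0 = %g ps), peak %.2f mV\n",
              length(x$samples), x$dt, x$t0,
              if (length(x$samples)) max(x$samples) else NA_real_))
  invisible(x)
}

#' Sample times of a waveform
#' @param wf A [waveform()].
#' @return Numeric vector of sample times in ps.
#' @export
waveform_times <- function(wf) {
  stopifnot(inherits(wf, "waveform"))
  wf$t0 + (seq_along(wf$samples) - 1) * wf$dt
}

#' @export
plot.waveform <- function(x, ...) {
  graphics::plot(waveform_times(x), x$samples, type = "l",
                 xlab = "time (ps)", ylab = "amplitude (mV)", ...)
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$t0, b$t0)) && isTRUE(all.equal(a$dt, b$dt)) &&
    length(a$samples) == length(b$samples)
}

#' Render an analog timing waveform from photon arrivals
#'
#' Linear superposition of one SPAD pulse per arrival, evaluated exactly at
#' the sample times, plus optional white Gaussian noise. With no arrivals
#' and zero noise the trace is identically zero.
#'
#' @param arrivals Numeric vector of photon arrival times, ps.
#' @param template A [pulse_template()].
#' @param t0 Time of the first sample, ps.
#' @param n_samples Number of samples.
#' @param dt Sampling step, ps (default 80).
#' @param noise_sigma Gaussian noise sigma in mV (>= 0, default 0).
#' @param seed Optional integer seed for the noise.
#' @return A [waveform()].
#' @examples
#' wf <- render_waveform(c(1000), single_spad_template(), t0 = 0,
#'                       n_samples = 100)
#' max(wf$samples)
#' @export
render_waveform <- function(arrivals, template, t0, n_samples, dt = 80,
                            noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(template, "pulse_template"))
  if (!is.numeric(noise_sigma) || length(noise_sigma) != 1L || noise_sigma < 0)
    stop("'noise_sigma' must be >= 0", call. = FALSE)
  if (dt <= 0) stop("'dt' must be > 0", call. = FALSE)
  n_samples <- as.integer(n_samples)
  samples <- numeric(n_samples)
  t_end <- t0 + (n_samples - 1L) * dt
  arrivals <- arrivals[is.finite(arrivals) & arrivals < t_end]
  if (length(arrivals) > 0) {
    # The bi-exponential pulse is a difference of one-pole responses, so the
    # superposition over arrivals is rendered exactly by two recursive
    # filters: each arrival injects its phase factor at the first sample at
    # or after it, and the recursion exp(-dt/tau) propagates it onward.
    tr <- template$rise_tau
    td <- template$decay_tau
    peak_t <- log(td / tr) * tr * td / (td - tr)
    peak_v <- exp(-peak_t / td) - exp(-peak_t / tr)
    j0 <- pmax(floor((arrivals - t0) / dt) + 2L, 1L)
    lag <- t0 + (j0 - 1L) * dt - arrivals     # >= 0, time into the pulse
    inj_d <- numeric(n_samples)
    inj_r <- numeric(n_samples)
    acc_d <- rowsum(exp(-lag / td), group = j0)
    acc_r <- rowsum(exp(-lag / tr), group = j0)
    at <- as.integer(rownames(acc_d))
    inj_d[at] <- acc_d[, 1L]
    inj_r[at] <- acc_r[, 1L]
    s_d <- as.numeric(stats::filter(inj_d, exp(-dt / td),
                                    method = "recursive"))
    s_r <- as.numeric(stats::filter(inj_r, exp(-dt / tr),
                                    method = "recursive"))
    samples <- template$amplitude * (s_d - s_r) / peak_v
  }
  if (noise_sigma > 0)
    samples <- samples + with_seed(seed, stats::rnorm(n_samples, 0, noise_sigma))
  waveform(samples, t0 = t0, dt = dt)
}

#' Inject electronic crosstalk between the two pixel waveforms
#'
#' In the common-cathode segmented readout, the activation of one pixel
#' induces a deflection of opposite polarity in the other pixel. Each onset
#' time in `activity` injects, into the opposite pixel and after
#' `electronic_delay`, a bipolar pulse: a negative lobe followed by a
#' recovery rebound `rebound_lag` later, normalized so the rebound peak
#' equals `electronic_amplitude_fraction` times the single-SPAD amplitude.
#' A leading-edge discriminator therefore fires on the rebound only while
#' its threshold is below that amplitude. With fraction 0 the waveforms are
#' returned unchanged.
#'
#' @param wf_A,wf_B Pixel waveforms on the same grid.
#' @param activity A list with numeric vectors `A` and `B` of signal onset
#'   times (ps) in each pixel (typically the first-arrival or trigger time).
#' @param cfg A [crosstalk_config()].
#' @param template The [pulse_template()] whose amplitude defines the
#'   single-SPAD scale (default segmented).
#' @return A list with modified waveforms `A` and `B`.
#' @export
inject_electronic_crosstalk <- function(wf_A, wf_B, activity, cfg,
                                        template = single_spad_template()) {
  stopifnot(inherits(wf_A, "waveform"), inherits(wf_B, "waveform"),
            inherits(cfg, "crosstalk_config"))
  if (!same_grid(wf_A, wf_B))
    stop("waveforms must share t0, dt and length", call. = FALSE)
  if (!is.list(activity) || !all(c("A", "B") %in% names(activity)))
    stop("'activity' must be a list with elements A and B", call. = FALSE)
  if (cfg$electronic_amplitude_fraction == 0) return(list(A = wf_A, B = wf_B))
  add_xt <- function(wf, onsets) {
    onsets <- onsets[is.finite(onsets)]
    if (length(onsets) == 0) return(wf)
    tt <- waveform_times(wf)
    extra <- numeric(length(tt))
    for (on in onsets) {
      shape <- crosstalk_shape(tt - on - cfg$electronic_delay, cfg, template)
      extra <- extra + shape
    }
    waveform(wf$samples + extra, t0 = wf$t0, dt = wf$dt)
  }
  list(A = add_xt(wf_A, activity$B), B = add_xt(wf_B, activity$A))
}

# bipolar crosstalk shape: -pulse(t) + pulse(t - rebound_lag), rescaled so the
# positive rebound peak equals fraction * single-SPAD amplitude
crosstalk_shape <- function(t, cfg, template) {
  raw <- function(x) pulse_eval(x - cfg$rebound_lag, template) -
    pulse_eval(x, template)
  grid <- seq(0, pulse_span(template) + cfg$rebound_lag, by = 10)
  peak <- max(raw(grid))
  target <- cfg$electronic_amplitude_fraction * template$amplitude
  raw(t) * target / peak
}

#' Inject optical crosstalk at the photon-arrival level
#'
#' Light escaping one pixel's pathway can fire SPADs of the neighbouring
#' pixel after crossing the crystal, so each detected photon spawns, with
#' probability `optical_prob`, a secondary arrival in the opposite pixel
#' lagged by `optical_delay_per_mm * crystal_length` (with relative Gaussian
#' jitter `optical_jitter_frac`, truncated positive). Secondary arrivals are
#' tagged `"optical_crosstalk"`.
#'
#' @param arrivals_A,arrivals_B Per-pixel arrival data.frames with columns
#'   `time_ps` and `origin`.
#' @param cfg A [crosstalk_config()].
#' @param crystal_length Crystal length in mm.
#' @param seed Optional integer seed.
#' @return A list with augmented data.frames `arrivals_A` and `arrivals_B`.
#' @export
inject_optical_crosstalk <- function(arrivals_A, arrivals_B, cfg,
                                     crystal_length, seed = NULL) {
  stopifnot(inherits(cfg, "crosstalk_config"))
  if (cfg$optical_prob == 0)
    return(list(arrivals_A = arrivals_A, arrivals_B = arrivals_B))
  with_seed(seed, {
    lag_mean <- cfg$optical_delay_per_mm * crystal_length
    spawn <- function(src) {
      hit <- stats::runif(nrow(src)) < cfg$optical_prob
      n <- sum(hit)
      if (n == 0L)
        return(data.frame(time_ps = numeric(0), origin = character(0),
                          stringsAsFactors = FALSE))
      lag <- lag_mean * abs(1 + stats::rnorm(n, 0, cfg$optical_jitter_frac))
      data.frame(time_ps = src$time_ps[hit] + lag,
                 origin = "optical_crosstalk", stringsAsFactors = FALSE)
    }
    sec_to_B <- spawn(arrivals_A)
    sec_to_A <- spawn(arrivals_B)
    list(
      arrivals_A = rbind(arrivals_A[c("time_ps", "origin")], sec_to_A),
      arrivals_B = rbind(arrivals_B[c("time_ps", "origin")], sec_to_B)
    )
  })
}

#' Merged energy integral of the two pixel waveforms
#'
#' The two energy signals are merged into one by sample-wise summation and
#' integrated over the full trace (rectangle rule, `sum * dt`), giving a
#' charge in mV*ps proportional to the number of detected photons for a
#' noise-free linear system.
#'
#' @param wf_A,wf_B Pixel waveforms on the same grid.
#' @return Charge in mV*ps.
#' @export
merged_energy_integral <- function(wf_A, wf_B) {
  stopifnot(inherits(wf_A, "waveform"), inherits(wf_B, "waveform"))
  if (!same_grid(wf_A, wf_B))
    stop("waveforms must share t0, dt and length", call. = FALSE)
  sum(wf_A$samples + wf_B$samples) * wf_A$dt
}
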