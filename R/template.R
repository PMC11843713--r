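#' SPAD pulse template
#'
#' A bi-exponential single-SPAD pulse, `amplitude * (exp(-t/decay_tau) -
#' exp(-t/rise_tau))` normalized so its peak equals `amplitude` (mV). The
#' segmentation mode records which detector configuration the template
#' represents.
#'
#' @param amplitude Peak amplitude in mV per fired SPAD (>= 0).
#' @param rise_tau Rise time constant in ps (must be < `decay_tau`).
#' @param decay_tau Decay time constant in ps.
#' @param segmentation_mode One of `"segmented"`, `"connected"`,
#'   `"nonsegmented"`.
#' @param bias_scale Dimensionless multiplier standing in for the SiPM bias
#'   voltage; the stored `amplitude` already includes it.
#'
#' @return An object of class `pulse_template`.
#' @export
pulse_template <- function(amplitude, rise_tau, decay_tau,
                           segmentation_mode = "segmented", bias_scale = 1) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("'amplitude' must be >= 0 mV", call. = FALSE)
  if (rise_tau <= 0 || decay_tau <= 0 || rise_tau >= decay_tau)
    stop("need 0 < rise_tau < decay_tau", call. = FALSE)
  segmentation_mode <- match.arg(segmentation_mode,
                                 c("segmented", "connected", "nonsegmented"))
  structure(list(amplitude = amplitude, rise_tau = rise_tau,
                 decay_tau = decay_tau, segmentation_mode = segmentation_mode,
                 bias_scale = bias_scale),
            class = "pulse_template")
}

#' @export
print.pulse_template <- function(x, ...) {
  cat(sprintf("<pulse_template> %s: %.2f mV, rise %g ps, decay %g ps (bias x%g)\n",
              x$segmentation_mode, x$amplitude, x$rise_tau, x$decay_tau,
              x$bias_scale))
  invisible(x)
}

#' Single-SPAD pulse template for a detector configuration
#'
#' Returns the average fired-SPAD timing pulse for the three readout
#' configurations. The segmented pixel is the reference (26 mV, the typical
#' single-SPAD amplitude of a segmented pixel). Connecting the two pixel
#' anodes (`"connected"`) increases the parasitic capacitance, reducing the
#' amplitude to about two-thirds with a slower rise; a full-size
#' non-segmented SiPM (`"nonsegmented"`) drops below half with the slowest
#' rise. Amplitude scales monotonically with `bias_scale`.
#'
#' @param segmentation_mode `"segmented"`, `"connected"` or `"nonsegmented"`.
#' @param bias_scale Dimensionless bias-voltage proxy (>= 0, default 1).
#' @param reference_amplitude Segmented-pixel amplitude at `bias_scale = 1`
#'   in mV (default 26).
#' @param connected_factor,nonsegmented_factor Amplitude ratios of the
#'   connected and non-segmented configurations relative to segmented
#'   (defaults 0.67 and 0.45; only the ordering nonsegmented < connected <
#'   segmented is constrained by the measurements).
#'
#' @return A [pulse_template()].
#' @examples
#' single_spad_template("segmented")$amplitude  # 26
#' @export
single_spad_template <- function(segmentation_mode = c("segmented", "connected",
                                                       "nonsegmented"),
                                 bias_scale = 1,
                                 reference_amplitude = 26,
                                 connected_factor = 0.67,
                                 nonsegmented_factor = 0.45) {
  segmentation_mode <- match.arg(segmentation_mode)
  if (!is.numeric(bias_scale) || length(bias_scale) != 1L || bias_scale < 0)
    stop("'bias_scale' must be >= 0", call. = FALSE)
  pars <- switch(segmentation_mode,
    segmented    = list(factor = 1,                   rise = 200, decay = 1500),
    connected    = list(factor = connected_factor,    rise = 400, decay = 2250),
    nonsegmented = list(factor = nonsegmented_factor, rise = 600, decay = 3000)
  )
  pulse_template(amplitude = reference_amplitude * pars$factor * bias_scale,
                 rise_tau = pars$rise, decay_tau = pars$decay,
                 segmentation_mode = segmentation_mode,
                 bias_scale = bias_scale)
}

#' Evaluate a pulse template
#'
#' Pulse value in mV at times `t` (ps) after the SPAD firing; zero for
#' `t < 0`. The bi-exponential shape is normalized so that its maximum is
#' the template amplitude.
#'
#' @param t Numeric vector of times since firing, ps.
#' @param template A [pulse_template()].
#' @return Numeric vector of the same length as `t`.
#' @export
pulse_eval <- function(t, template) {
  stopifnot(inherits(template, "pulse_template"))
  tr <- template$rise_tau
  td <- template$decay_tau
  peak_t <- log(td / tr) * tr * td / (td - tr)
  peak_v <- exp(-peak_t / td) - exp(-peak_t / tr)
  v <- ifelse(t > 0, exp(-t / td) - exp(-t / tr), 0)
  template$amplitude * v / peak_v
}

# full integral of the normalized pulse: amplitude * (decay - rise) / peak_v
pulse_full_integral <- function(template) {
  tr <- template$rise_tau
  td <- template$decay_tau
  peak_t <- log(td / tr) * tr * td / (td - tr)
  peak_v <- exp(-peak_t / td) - exp(-peak_t / tr)
  template$amplitude * (td - tr) / peak_v
}

# time after which the pulse is negligible; used to bound rendering kernels
pulse_span <- function(template) {
  peak_t <- log(template$decay_tau / template$rise_tau) *
    template$rise_tau * template$decay_tau /
    (template$decay_tau - template$rise_tau)
  peak_t + 8 * template$decay_tau
}
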