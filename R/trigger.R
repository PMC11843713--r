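#' Leading-edge timestamp of a waveform
#'
#' Returns the time of the first upward crossing of `threshold`, linearly
#' interpolated between the two samples bracketing the crossing, matching
#' common oscilloscope post-processing. `NA` if the trace never reaches the
#' threshold.
#'
#' @param wf A [waveform()].
#' @param threshold Discrimination threshold in mV (> 0).
#' @return Crossing time in ps, or `NA_real_`.
#' @examples
#' ramp <- waveform(seq(0, 10, length.out = 101), t0 = 0, dt = 1)
#' leading_edge_timestamp(ramp, 5)  # 50
#' @export
leading_edge_timestamp <- function(wf, threshold) {
  stopifnot(inherits(wf, "waveform"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("'threshold' must be a positive voltage in mV", call. = FALSE)
  s <- wf$samples
  above <- s >= threshold
  if (!any(above)) return(NA_real_)
  i <- which.max(above)            # first sample at/above threshold
  if (i == 1L) return(wf$t0)       # already above at trace start
  frac <- (threshold - s[i - 1L]) / (s[i] - s[i - 1L])
  wf$t0 + (i - 2L + frac) * wf$dt
}

#' Adaptive timestamp pickoff
#'
#' Selects the earlier of the two pixel timestamps with a margin `k`:
#' `T_A` is taken when `T_A - T_B <= k`, otherwise `T_B`. With `k = 0` this
#' is `min(T_A, T_B)`; the rule is symmetric under swapping the pixels with
#' `k -> -k`. When only one timestamp is defined the defined one is
#' returned; when neither is, `NA`.
#'
#' @param T_A,T_B Pixel timestamps in ps (may be `NA`); vectorized.
#' @param k Margin in ps (default 0).
#' @param rule `"le"` (default) uses `T_A - T_B <= k`; `"lt"` uses strict
#'   `<`. The two differ only when `T_A - T_B` equals `k` exactly.
#' @return Selected timestamps, ps.
#' @examples
#' adaptive_timestamp(100, 200)      # 100
#' adaptive_timestamp(300, 200, 150) # 200
#' @export
adaptive_timestamp <- function(T_A, T_B, k = 0, rule = c("le", "lt")) {
  rule <- match.arg(rule)
  n <- max(length(T_A), length(T_B))
  T_A <- rep_len(as.numeric(T_A), n)
  T_B <- rep_len(as.numeric(T_B), n)
  d <- T_A - T_B
  pick_a <- if (rule == "le") d <= k else d < k
  out <- ifelse(pick_a, T_A, T_B)
  out[is.na(T_A)] <- T_B[is.na(T_A)]
  out[is.na(T_B)] <- T_A[is.na(T_B)]
  out
}

#' Trigger time difference between the two pixels
#'
#' `T_A - T_B` when both timestamps are defined, `NA` otherwise. Its
#' distribution over events carries the temporal density of the first
#' detected photons: Cherenkov-triggered events pile up near zero while
#' scintillation-triggered events spread over thousands of ps.
#'
#' @param T_A,T_B Pixel timestamps in ps; vectorized.
#' @return `T_A - T_B` in ps, `NA` where either input is missing.
#' @export
trigger_time_difference <- function(T_A, T_B) {
  as.numeric(T_A) - as.numeric(T_B)
}

#' Timestamp both pixels of an event and combine them
#'
#' Convenience wrapper producing the per-event trigger result: both
#' leading-edge timestamps, the adaptive timestamp and the trigger time
#' difference.
#'
#' @param wf_A,wf_B Pixel waveforms.
#' @param threshold Leading-edge threshold in mV.
#' @param k Adaptive pickoff margin in ps (default 0).
#' @return A list with `T_A`, `T_B`, `T_adaptive`, `delta_T`, `threshold`
#'   and `k_margin` (class `trigger_result`).
#' @export
trigger_event <- function(wf_A, wf_B, threshold, k = 0) {
  T_A <- leading_edge_timestamp(wf_A, threshold)
  T_B <- leading_edge_timestamp(wf_B, threshold)
  structure(list(
    T_A = T_A, T_B = T_B,
    T_adaptive = adaptive_timestamp(T_A, T_B, k),
    delta_T = trigger_time_difference(T_A, T_B),
    threshold = threshold, k_margin = k
  ), class = "trigger_result")
}

#' @export
print.trigger_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else sprintf("%.1f ps", v)
  cat(sprintf("<trigger_result> T_A = %s, T_B = %s, adaptive = %s, dT = %s\n",
              fmt(x$T_A), fmt(x$T_B), fmt(x$T_adaptive), fmt(x$delta_T)))
  invisible(x)
}
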