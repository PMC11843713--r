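---
title: "Segmented-readout timing analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented-readout timing analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(segtof)
```

This vignette documents the physical model behind `segtof`, the parameters
that matter and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## The detector model

A 511 keV annihilation photon interacting in a BGO crystal produces two
photon populations:

* **Cherenkov photons** — prompt (picoseconds), Poisson with mean 17 at
  511 keV. Their yield falls with deposited energy; `segtof` uses a linear
  rule above a 50 keV threshold (the recoil electron must exceed the
  Cherenkov threshold of the medium). Only the monotone direction of this
  dependence matters for the analyses; the exact functional form is a
  modelling choice, exposed in `physics_config()`.
* **Scintillation photons** — Poisson with mean 4000 at 511 keV, scaling
  linearly with energy, emitted with a rise/decay biexponential. BGO time
  constants are not part of the measured inputs, so the defaults are
  literature-style values (`scint_rise_tau = 300` ps,
  `scint_decay_tau = 300` ns) and must be treated as configurable
  placeholders, not assertions. Emission times are sampled exactly as the
  sum of one exponential rise delay and one exponential decay delay, whose
  density is the normalized difference of exponentials.

**Transport and detection.** Each photon independently survives with
probability `detection_prob * exp(-loss_per_mm * crystal_length)`;
survivors fall on pixel A with `pixel_split_fraction` (0.5 for the
symmetric detector) and acquire an exponential transit-delay tail with
mean `transit_spread_per_mm * crystal_length`. The per-mm loss (0.015) and
transit spread (5 ps/mm) are chosen so that a 15 mm crystal detects on the
order of 3–5 initial photons per coincidence — the scale observed for this
detector class — and so that mean detected counts strictly decrease with
length. The black-reflector mode multiplies survival by 0.6 and the
transit spread by 0.3: an absorbing wrap removes reflected, long-path
photons, trading photon count for reduced time dispersion.

**The reference detector** is modelled at the timestamp level only:
Gaussian jitter of 83 ps FWHM on the interaction time. Its waveform adds
nothing to the analyses here, and its measured resolution enters only as a
quadrature term (`subtract_reference()`, off by default — CTRs are
reported as measured).

**Thinning-first sampling.** `simulate_coincidence_stream()` draws the
*detected* photon count per pixel directly from the thinned Poisson law
and samples times only for survivors. This is statistically identical to
emitting all ~4000 photons and transporting them — survival marks are
independent of emission times — and is what makes 10^5-event streams
affordable. The explicit path (`fast = FALSE`) is kept and the equivalence
is tested (moments and Kolmogorov–Smirnov on arrival times). For studies
that use only timestamps, `max_time` truncates arrivals beyond the trace;
full-stream charge integrals must not use it.

## Waveforms and triggering

Each fired SPAD contributes a bi-exponential pulse normalized so its peak
is the template amplitude. The segmented pixel is the 26 mV reference;
connecting the two pixel anodes scales it to 0.67 with a slower rise, and
a full-size non-segmented SiPM to 0.45 with the slowest rise — the
measurements constrain only the *ordering* (nonsegmented < connected <
segmented; "decreased by two-thirds" is read as decreased *to*
two-thirds, since the nonsegmented value must lie below it), so the exact
ratios are tunable defaults. Rise/decay defaults (200/1500 ps segmented)
make the pulse peak within 1 ns, consistent with the capacitance argument
for segmentation.

Rendering evaluates the superposition exactly on the 80 ps (12.5 GS/s)
sample grid: because the pulse is a difference of one-pole responses, the
sum over arrivals is computed by two recursive filters, which is exact
(verified against brute-force superposition at 1e-13) and linear in trace
length. White Gaussian noise (default 1 mV) is added per sample; no ADC
quantizer or bandwidth limit is applied by default.

Timestamps are leading-edge: the first upward threshold crossing,
linearly interpolated between the bracketing samples (standard
oscilloscope post-processing; tested against a 100x oversampled
brute-force finder). The default threshold of 13 mV is half a segmented
single-SPAD amplitude, i.e. a single-photon trigger with headroom above
the noise. The adaptive pickoff implements `T_A` if `T_A − T_B ≤ k`, else
`T_B`. This is the reading of the selection rule that reproduces both
stated behaviours — "earlier timestamp with margin k" and the `k = 0`
optimum — and at the operating point `k = 0` the `≤` versus `<` variants
coincide except on measure-zero ties; both are available (`rule=`). When
only one pixel crosses threshold, the adaptive timestamp falls back to
the defined one and the event is excluded from ΔT-based selections (its
initial count on the silent side is zero).

## Initial photon counting

Each pixel's trace is integrated over 1 ns from its **own** trigger time
(a per-pixel window matches the per-signal onset; a switch
`start_mode = "earlier_trigger"` implements the alternative reading, with
no qualitative change to the analyses). The charge histogram is quantized
on the single-photon grid; the pitch is estimated by a density first-peak
guess, refined by maximizing the phase-alignment score
`mean(cos(2*pi*q/u))`, then by averaging `q/round(q/u)` over grid-assigned
charges. This is robust to the smear between grid lines caused by
late-arriving photons whose response leaks past the window end. Counts are
the nearest non-negative integer on the grid (the rounding rule is not
dictated by the charge spectrum itself; nearest-integer is symmetric and
is the convention used throughout). The 300 ps trigger-time-window rule
zeroes the count of a pixel that starts more than 300 ps after its
neighbour; the boundary at exactly the window is *not* zeroed — an
arbitrary but fixed and documented convention — and the rule is idempotent
and symmetric.

## Width estimation and classification

Histograms default to 25 ps bins (roughly FWHM/5–FWHM/7 at the scales
produced here; configurable). `fwhm_fwtm()` offers:

* `gauss_fit` (default): FWHM from a Gaussian fit to the peak core (bins
  within 1.5 direct-FWHM of the peak), FWTM always measured directly at
  10% of peak height by linear interpolation. The measured FWTM/FWHM
  ratios of hybrid emitters far exceed the Gaussian 1.83, so a
  fitted FWTM would misrepresent the tails; conversely the core fit
  stabilizes the FWHM against bin noise.
* `direct`: both widths interpolated from the binned curve, scanning
  outward from the peak to the first crossing.

FWTM is floored at FWHM (the 10% width cannot be narrower). Decile
classification ranks `|ΔT|` with ties broken by stable event order, giving
classes equal within one event; `n_groups = 1` reproduces the global CTR.
All statistics are descriptive widths — no multiple-testing machinery is
involved.

`side_peak_locator()` finds local maxima of the lightly smoothed ΔT
histogram outside the central peak. Side-peak analyses here use a heavier
smoothing (±2 bins) and a 10% height cut, which on 8,000–10,000-event
streams cleanly separates genuine crosstalk peaks from shoulder
fluctuations of the broad scintillation background.

## Crosstalk mechanisms

The two mechanisms have deliberately different injection points, matching
their different signatures:

* **Electronic crosstalk** (waveform level, length-independent): each
  signal onset injects into the *other* pixel, after `electronic_delay`,
  a bipolar pulse — a negative lobe followed by a recovery rebound —
  normalized so the rebound peak is `electronic_amplitude_fraction` times
  the single-SPAD amplitude. The common-cathode current-sinking produces
  the opposite-polarity deflection; the recovery rebound is what a
  positive-threshold leading-edge discriminator can capture, and it
  vanishes as soon as the threshold exceeds the crosstalk amplitude.
  One injection per onset (not per fired SPAD) keeps the crosstalk
  amplitude at the observed sub-SPAD scale.
* **Optical crosstalk** (arrival level, length-dependent): each detected
  photon spawns, with `optical_prob`, a secondary arrival in the opposite
  pixel lagged by `optical_delay_per_mm * crystal_length` (15% relative
  jitter). Doubling the length doubles the mean lag, so the first side
  peaks move outward with crystal length while electronic peaks stay put.

Both default to off in `process_events()` (pass a `crosstalk_config()` to
enable); the bundled fixtures include a crosstalk-on dataset.

## What the generator does and does not emulate

Emulated: Poisson photon statistics and their energy scaling,
scintillation kinetics, length-dependent transport loss and transit
spread, binomial pixel splitting, segmentation-dependent pulse shapes,
digitization at 12.5 GS/s, reference jitter, both crosstalk mechanisms,
photopeak-only and flat-continuum energy spectra (the continuum is a
selection-logic stand-in, not a physical Compton transport model).

Not emulated: optical ray tracing and wavelength-resolved detection
efficiency, SPAD-level spatial structure, afterpulsing and dark counts,
ADC quantization, amplifier bandwidth. Consequently, passing tests
demonstrate that the *analysis chain* behaves correctly and that the
directional relations (photon number vs length, vs energy, vs |ΔT|; CTR
vs photon number; side-peak phenomenology) emerge from the assumed
physics — they do not certify absolute agreement with any physical
detector, whose measured CTR values depend on hardware specifics outside
this model.

## Numerical and experimental design choices

* **Problem sizes.** The bundled experiments use 2x10^4-3x10^4
  coincidences for CTR sweeps (the optimum-k argmin is stable at this
  size; the FWHM difference between k = 0 and ±25 ps is below a
  picosecond, but the sweep reuses one event set so adjacent-k noise is
  strongly correlated and the parabola resolves cleanly), 5x10^3 per
  crystal length for photon-count trends, 8x10^3 per crosstalk
  configuration, and 10^5 arrival-level events for the Poisson
  goodness-of-fit.
* **1/sqrt(N) scaling.** The photon-statistics law is asymptotic: with a
  linear-in-time density at signal onset (finite rise time), the first
  detected photon's spread scales as N^(-1/2) only once that spread sits
  well inside the rise constant. `ctr_scaling_exponent()` therefore
  sweeps high scintillation-only yields (4x10^4-1.6x10^5) with truncated
  streams, and measures widths with the direct estimator, which is
  stabler than a core fit for these skewed distributions. At BGO-like
  yields the effective exponent is visibly steeper than -1/2 — expected,
  not a defect.
* **Energy calibration** anchors the right-most substantial density peak
  of the merged charge integrals at 511 keV. With the default 32 ns trace
  only ~10% of the scintillation light is integrated, so the simulated
  energy resolution (~20%) is much worse than a real full-integration
  energy channel; the 400–600 keV window then acts as a soft photopeak
  selection. This affects efficiency, not correctness, of the
  photopeak-mode analyses.
* **Degenerate inputs.** Empty histograms, flat traces, all-equal charge
  spectra, zero-event streams and one-sided triggers all have defined
  behaviour (errors with clear messages, or documented fallbacks) and are
  tested.
* **Seeds.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state; manifests record the seeds, so any
  persisted run can be reproduced bit-for-bit.

## Known limitations

The crosstalk amplitude model is phenomenological (one bipolar pulse per
onset); real electronic coupling depends on the instantaneous current of
the whole pixel. The flat continuum under-represents forward-peaked
Compton kinematics. The pitch estimator assumes at least a visible
single-photon cluster; spectra dominated by >10-photon events would need
the phase-score search widened. And the absolute CTR values produced by
the defaults are properties of the chosen model constants, not
predictions for any particular hardware.
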