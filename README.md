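# segtof

Simulation and event-level timing analysis for a hybrid
Cherenkov/scintillation TOF-PET detector with a **segmented SiPM readout**:
one BGO crystal coupled to two small SiPM pixels (A and B) instead of one
large pixel.

## The problem

Bismuth germanate (BGO) emits two photon populations per 511 keV
annihilation photon: a handful of prompt Cherenkov photons (mean ~17,
within picoseconds) and ~4000 slow scintillation photons (hundreds of
nanoseconds). Timing an event on a Cherenkov photon gives excellent
coincidence timing resolution (CTR); timing it on a scintillation photon
gives a poor one. Because the Cherenkov count fluctuates event by event,
the detector does not have *one* timing resolution but a mixture of
kernels — a problem for time-of-flight reconstruction.

Reading the crystal with two segmented pixels yields two leading-edge
timestamps `T_A`, `T_B` and two charges per event. This package implements
the analysis built on that idea, for detector physicists studying
event-dependent timing:

* **Adaptive timestamp pickoff** — select the earlier timestamp with a
  margin `k`: `T = T_A` if `T_A − T_B ≤ k`, else `T_B` (`k = 0` is the
  minimum rule, and is the optimum for a symmetric detector).
* **Trigger time difference** `ΔT = T_A − T_B` — small `|ΔT|` flags a high
  initial photon density (likely Cherenkov-triggered events).
* **Initial photon number** — integrate the first 1 ns of each timing
  signal, calibrate the single-photon charge grid from the quantized
  charge spectrum, round to photon counts, and zero the count of a pixel
  that triggers more than 300 ps after its neighbour.
* **Timing kernels** — CTR (FWHM/FWTM) of the time difference to an 83 ps
  FWHM reference detector, swept versus `k` and versus the selection
  window `ΔT_k`, and tabulated per `|ΔT|` decile and per initial photon
  number for multikernel reconstruction.
* A **Monte Carlo generator** of coincidence waveforms (photon emission,
  transport loss and transit spread versus crystal length, binomial pixel
  splitting, segmentation-dependent SPAD pulses at 12.5 GS/s, electronic
  and optical crosstalk) standing in for oscilloscope data.

Detector resolutions combine in quadrature, `CTR_ij² = R_i² + R_j²`;
`solve_pair_resolutions()` inverts three pairwise measurements exactly.

## Worked example

```r
library(segtof)

cfg <- physics_config()            # 15 mm BGO, white wrap, photopeak source
st  <- simulate_coincidence_stream(cfg, 5000, seed = 1)
rec <- process_events(st, seed = 2)

mean(rec$n_total)                  # mean initial photon number
sel <- energy_window_filter(rec, 400, 600)
vk  <- ctr_vs_k(sel, k_grid = seq(-500, 500, by = 100))
vk[, c("k_ps", "fwhm_ps", "fwtm_ps")]
```

Output from this exact run:

```
> mean(rec$n_total)
[1] 3.2714
> vk[, c("k_ps", "fwhm_ps", "fwtm_ps")]
   k_ps  fwhm_ps  fwtm_ps
1  -500 152.4464 316.5720
2  -400 152.3817 316.6844
3  -300 152.1281 316.9782
4  -200 151.0971 308.2500
5  -100 140.0942 285.5790
6     0 130.3193 277.1610
7   100 139.7611 284.0404
8   200 148.4761 310.0680
9   300 150.5985 320.4255
10  400 150.9378 319.4715
11  500 151.3119 320.5171
```

Each event detects on average ~3.3 photons in its first nanosecond. The
CTR-vs-`k` curve dips to its minimum FWHM (~130 ps here, reference jitter
included) at `k = 0`: picking the earlier of the two pixel timestamps is
optimal for a symmetric detector, and both FWHM and FWTM improve over the
single-pixel selections at `k = ±500` because late
scintillation-triggered timestamps are replaced. The FWTM/FWHM ratio
(~2.1) above the Gaussian 1.83 reflects the mixed
Cherenkov/scintillation kernel; selecting small-`|ΔT|` events
(`ctr_vs_dtk()`) drives it back toward 1.83.

A thin command-line wrapper with `simulate`, `analyze`, `fixtures` and
`sweep` subcommands lives at `inst/cli/segtof.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/segtof.R", package="segtof"))')" \
    simulate --n-events 10000 --seed 1 --out runs/sim
```

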