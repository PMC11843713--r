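Package: segtof
Title: Segmented-Readout Timing Analysis for Hybrid Cherenkov/Scintillation TOF-PET Detectors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte Carlo generation and event-level analysis of coincidence
    timing data from a bismuth germanate (BGO) time-of-flight PET detector read
    out by two segmented silicon-photomultiplier (SiPM) pixels. Simulates the
    hybrid Cherenkov/scintillation photon emission, photon transport and
    detection, SPAD pulse synthesis with electronic and optical crosstalk, and
    digitized waveform formation; extracts per-pixel leading-edge timestamps,
    combines them with an adaptive pickoff rule, counts initially detected
    photons by early-signal charge integration on the single-photon grid, and
    estimates coincidence timing resolution (FWHM/FWTM) with event
    classification into trigger-time-difference and photon-number timing
    kernels for multikernel reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
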