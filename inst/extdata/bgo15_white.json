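{
  "mean_cherenkov_photons": 17,
  "mean_scint_photons": 4000,
  "scint_decay_tau": 300000,
  "scint_rise_tau": 300,
  "cherenkov_spread": 2,
  "light_yield_energy_scaling": "linear",
  "cherenkov_energy_scaling": "linear",
  "cherenkov_energy_threshold": 50,
  "crystal_length": 15,
  "transit_spread_per_mm": 5,
  "loss_per_mm": 0.015,
  "detection_prob": 0.2,
  "pixel_split_fraction": 0.5,
  "reflector_mode": "white",
  "black_survival_factor": 0.6,
  "black_spread_factor": 0.3,
  "energy_mode": "photopeak_only",
  "photopeak_fraction": 0.6,
  "compton_edge": 340
}
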