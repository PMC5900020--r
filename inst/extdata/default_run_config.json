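{
  "geometry": {
    "sheet_size": 30,
    "scar_diameter": 10,
    "bz_thickness": 2,
    "resolution": 0.05,
    "bz_fiber_mode": "horizontal",
    "random_seed": 1
  },
  "tissue": {
    "beta": 0.14,
    "Cm": 1,
    "dt": 0.02,
    "sample_dt": 1,
    "stimulus_amplitude": null,
    "stimulus_duration": 2,
    "cycle_length": 500,
    "n_beats": 5,
    "record_from_beat": 5,
    "rev_update_every": 25,
    "cg_tol": 1e-06
  },
  "conductivity_presets": {
    "normal_anisotropic": {
      "sigma_l": 0.189,
      "sigma_t": 0.069
    },
    "decreased_transverse": {
      "sigma_l": 0.189,
      "sigma_t": 0.0069
    },
    "decreased_isotropic": {
      "sigma_l": 0.0689,
      "sigma_t": 0.0689
    }
  }
}
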