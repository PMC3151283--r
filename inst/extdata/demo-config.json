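{
  "stages": ["simulate", "frap", "junctions", "assay"],
  "seed": 42,
  "frap": {
    "prebleach_mean": 1000,
    "bleach_depth": 0.2,
    "mobile_fraction_true": 0.5,
    "tau_true": 0.05,
    "photofade_rate": 0.002,
    "noise_sd_frac": 0.02,
    "n_traces": 12,
    "condition": "basal"
  },
  "junctions": {
    "image_size": [256, 256],
    "n_junctions_pos": 15,
    "n_junctions_neg": 15,
    "junction_intensity_pos": 4,
    "junction_intensity_neg": 8,
    "marker_intensity_pos": 8,
    "background": 1,
    "noise_sd": 0.2
  },
  "assay": {
    "cell_means": [[1.0, 1.8], [1.0, 2.6]],
    "levelsA": ["MCF7", "FLCARMCF7"],
    "levelsB": ["basal", "Ad5"],
    "n_replicates": 4,
    "noise_sd": 0.25,
    "design": "twoway"
  }
}
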