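{
  "name": "benchmark",
  "description": "Packaged synthetic benchmark session: 16x16 grid at 1250 um pitch (64 channels/cm^2), 300 s gait kinematics at 100 Hz, 1000 Hz acquisition, 12 tuned sources with 1.5 mm spatial scale, default noise model.",
  "seed": 1,
  "duration_s": 300,
  "fs": 1000,
  "grid": { "n_rows": 16, "n_cols": 16, "pitch_um": 1250, "diameter_um": 850 },
  "tuning": { "n_sources": 12, "spatial_scale_mm": 1.5, "source_amp_uV": 12, "baseline_hg_uV": 2 },
  "kinematics": { "profile": "gait", "fs_kin": 100 },
  "noise": {
    "one_over_f_scale": 8,
    "line_hz": 50,
    "line_amp": 15,
    "n_harmonics": 3,
    "common_mode_amp": 15,
    "white_rms": 2,
    "pink_exponent": 1
  },
  "run_config": {
    "seed": 1,
    "band": [70, 150],
    "bin_ms": 100,
    "notch_base": 50,
    "n_harmonics": 4,
    "target_fs": 500,
    "impedance_threshold": 1,
    "split_ratio": 0.7
  }
}
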