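{
  "_comment": "Calibrated generator presets, v1. sd units are arbitrary BOLD amplitude. global_sd scales the uniform (zero-eigenvalue) harmonic mode, modular_sd the low-frequency modular modes, fine_sd the remaining high-frequency modes; noise_sd is isotropic sensor noise.",
  "version": 1,
  "presets": {
    "awake":             {"global_sd": 3.0,  "modular_sd": 5.0,  "fine_sd": 0.3,  "noise_sd": 0.5,  "arousal_score": 11},
    "light_anaesthesia": {"global_sd": 2.2,  "modular_sd": 3.5,  "fine_sd": 0.7,  "noise_sd": 0.7,  "arousal_score": 3},
    "deep_anaesthesia":  {"global_sd": 1.0,  "modular_sd": 1.5,  "fine_sd": 1.5,  "noise_sd": 1.0,  "arousal_score": 0},
    "dbs_off":           {"global_sd": 1.0,  "modular_sd": 1.5,  "fine_sd": 1.5,  "noise_sd": 1.0,  "arousal_score": 0},
    "ct_low":            {"global_sd": 1.8,  "modular_sd": 2.8,  "fine_sd": 0.9,  "noise_sd": 0.8,  "arousal_score": 3},
    "ct_high":           {"global_sd": 2.8,  "modular_sd": 4.6,  "fine_sd": 0.4,  "noise_sd": 0.55, "arousal_score": 9},
    "vt_low":            {"global_sd": 1.05, "modular_sd": 1.55, "fine_sd": 1.45, "noise_sd": 1.0,  "arousal_score": 0},
    "vt_high":           {"global_sd": 1.0,  "modular_sd": 1.5,  "fine_sd": 1.5,  "noise_sd": 1.0,  "arousal_score": 0}
  }
}
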