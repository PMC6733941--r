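{
  "simulate": {
    "trajectories": {
      "n": 105,
      "params": {
        "t_E": 1.2, "t_L": 17.6, "E0": 0.46, "E_plateau": 0.22,
        "f_loss": 0.5, "I_tot0": 200, "t0": 90, "frame_dt": 0.05,
        "duration": 300
      }
    },
    "titration": {
      "hill": { "A": 0.43, "B": 0.12, "k": 0.39, "n": 2.0 },
      "noise_sd": 0.01,
      "replicates": 3
    },
    "qcmd": {
      "f_vesicle": 28, "gain_frac": 0.05, "loss_frac": 0.63,
      "overtone": 7, "noise_sd": 0
    }
  },
  "kinetics": { "label": "0% chol / 0.16 mM TX-100" },
  "titration": {},
  "qcmd": { "injection_time": 120 }
}
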