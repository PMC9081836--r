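{
  "comment": "Surrogate knee MTU geometry and Hill constants per muscle. lmt_poly are cubic coefficients a0..a3 of MTU length (m) vs knee flexion angle (rad, 0 = full extension). Hill constants follow the Gait2392 lower-limb model definition (biceps femoris = long head). Synthetic surrogate, not an OpenSim extraction.",
  "version": 1,
  "muscles": {
    "RF": {"fmax0_N": 1169, "lopt0_m": 0.084, "lslack_m": 0.346, "penn0_rad": 0.0873, "sign": 1,  "lmt_poly": [0.39970, 0.045, -0.010, 0.0008]},
    "VL": {"fmax0_N": 1871, "lopt0_m": 0.084, "lslack_m": 0.157, "penn0_rad": 0.0873, "sign": 1,  "lmt_poly": [0.21255, 0.042, -0.009, 0.0006]},
    "BF": {"fmax0_N": 896,  "lopt0_m": 0.109, "lslack_m": 0.341, "penn0_rad": 0.0,    "sign": -1, "lmt_poly": [0.46985, -0.028, 0.004, -0.0003]},
    "ST": {"fmax0_N": 410,  "lopt0_m": 0.201, "lslack_m": 0.262, "penn0_rad": 0.0873, "sign": -1, "lmt_poly": [0.48665, -0.035, 0.006, -0.0005]}
  }
}
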