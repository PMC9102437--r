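{
  "g_p0": 0.86,
  "d_MCL1": 16.4,
  "d_BCL2": 0.86,
  "d_BIM": 5.94,
  "d_NOXA": 32.8,
  "d_BAX": 1.38,
  "Kd_3": 2.0,
  "Kd_4": 22.0,
  "Kd_5": 40.0,
  "Kd_6": 2.5,
  "Kd_7": 68.0,
  "k_plus": 0.17,
  "k1": 43.2,
  "k2": 8.64,
  "a_BCL2": 0.11,
  "s_MCL1": 0.37,
  "s_BCL2": 0.53,
  "s_BIM": 0.49,
  "s_NOXA": 0.40,
  "gamma": 0.43,
  "K_BAX": 200,
  "hill_n": 3,
  "kappa": 1.78,
  "alpha": 10.0,
  "beta": 2.65
}
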