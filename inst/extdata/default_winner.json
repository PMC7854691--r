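{
  "e0": 1500,
  "f_max": 8,
  "tau": 1.55,
  "u_plus": 0.25,
  "u_minus": 0.25,
  "sigma_max": 25.167083333333333,
  "sigma_rest": 7.5501249999999999,
  "sigma_final": 20.133666666666667,
  "phi_ramp": 0.9,
  "phi_final": 0.2
}
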