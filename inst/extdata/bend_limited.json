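{
  "e0": 1500,
  "f_max": 4.25,
  "tau": 1.55,
  "u_plus": 0.25,
  "u_minus": 0.25,
  "sigma_max": 26.5,
  "sigma_rest": 7.95,
  "sigma_final": 21.2,
  "phi_ramp": 0.9,
  "phi_final": 0.2
}
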