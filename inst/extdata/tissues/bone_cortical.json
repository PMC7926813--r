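{
  "name": "bone_cortical",
  "label": "Bone (cortical)",
  "model": "cole_cole",
  "eps_inf": 2.5,
  "poles": [
    {
      "delta_eps": 10,
      "tau_s": 1.3263e-11,
      "alpha": 0.2
    },
    {
      "delta_eps": 180,
      "tau_s": 7.9577e-08,
      "alpha": 0.2
    },
    {
      "delta_eps": 5000,
      "tau_s": 0.000159155,
      "alpha": 0.2
    },
    {
      "delta_eps": 100000,
      "tau_s": 0.015915,
      "alpha": 0
    }
  ],
  "sigma_static_s_m": 0.02,
  "provenance": "Four-pole Cole-Cole parameters from the Gabriel et al. (1996) parametric survey of tissue dielectric properties, as distributed by the IFAC-CNR database."
}
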