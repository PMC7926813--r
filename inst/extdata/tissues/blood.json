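{
  "name": "blood",
  "label": "Blood",
  "model": "cole_cole",
  "eps_inf": 4,
  "poles": [
    {
      "delta_eps": 56,
      "tau_s": 8.377e-12,
      "alpha": 0.1
    },
    {
      "delta_eps": 5200,
      "tau_s": 1.32629e-07,
      "alpha": 0.1
    },
    {
      "delta_eps": 0,
      "tau_s": 0.000159155,
      "alpha": 0.2
    },
    {
      "delta_eps": 0,
      "tau_s": 0.015915,
      "alpha": 0
    }
  ],
  "sigma_static_s_m": 0.7,
  "provenance": "Four-pole Cole-Cole parameters from the Gabriel et al. (1996) parametric survey of tissue dielectric properties, as distributed by the IFAC-CNR database."
}
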