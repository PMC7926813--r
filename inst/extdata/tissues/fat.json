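{
  "name": "fat",
  "label": "Fat (not infiltrated)",
  "model": "cole_cole",
  "eps_inf": 2.5,
  "poles": [
    {
      "delta_eps": 3,
      "tau_s": 7.958e-12,
      "alpha": 0.2
    },
    {
      "delta_eps": 15,
      "tau_s": 1.5915e-08,
      "alpha": 0.1
    },
    {
      "delta_eps": 33000,
      "tau_s": 0.000159155,
      "alpha": 0.05
    },
    {
      "delta_eps": 10000000,
      "tau_s": 0.015915,
      "alpha": 0.01
    }
  ],
  "sigma_static_s_m": 0.01,
  "provenance": "Four-pole Cole-Cole parameters from the Gabriel et al. (1996) parametric survey of tissue dielectric properties, as distributed by the IFAC-CNR database."
}
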