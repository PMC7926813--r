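{
  "name": "skin_dry",
  "label": "Skin (dry)",
  "model": "cole_cole",
  "eps_inf": 4,
  "poles": [
    {
      "delta_eps": 32,
      "tau_s": 7.234e-12,
      "alpha": 0
    },
    {
      "delta_eps": 1100,
      "tau_s": 3.2481e-08,
      "alpha": 0.2
    },
    {
      "delta_eps": 0,
      "tau_s": 0.000159155,
      "alpha": 0.2
    },
    {
      "delta_eps": 0,
      "tau_s": 0.015915,
      "alpha": 0.2
    }
  ],
  "sigma_static_s_m": 0.0002,
  "provenance": "Four-pole Cole-Cole parameters from the Gabriel et al. (1996) parametric survey of tissue dielectric properties, as distributed by the IFAC-CNR database."
}
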