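{
  "name": "csf",
  "label": "Cerebrospinal fluid",
  "model": "cole_cole",
  "eps_inf": 4,
  "poles": [
    {
      "delta_eps": 65,
      "tau_s": 7.958e-12,
      "alpha": 0.1
    },
    {
      "delta_eps": 40,
      "tau_s": 1.592e-09,
      "alpha": 0
    },
    {
      "delta_eps": 0,
      "tau_s": 0.000159155,
      "alpha": 0
    },
    {
      "delta_eps": 0,
      "tau_s": 0.015915,
      "alpha": 0
    }
  ],
  "sigma_static_s_m": 2,
  "provenance": "Four-pole Cole-Cole parameters from the Gabriel et al. (1996) parametric survey of tissue dielectric properties, as distributed by the IFAC-CNR database."
}
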