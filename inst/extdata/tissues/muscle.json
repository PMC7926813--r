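{
  "name": "muscle",
  "label": "Muscle",
  "model": "cole_cole",
  "eps_inf": 4,
  "poles": [
    {
      "delta_eps": 50,
      "tau_s": 7.234e-12,
      "alpha": 0.1
    },
    {
      "delta_eps": 7000,
      "tau_s": 3.53678e-07,
      "alpha": 0.1
    },
    {
      "delta_eps": 1200000,
      "tau_s": 0.00031831,
      "alpha": 0.1
    },
    {
      "delta_eps": 25000000,
      "tau_s": 0.002274,
      "alpha": 0
    }
  ],
  "sigma_static_s_m": 0.2,
  "provenance": "Four-pole Cole-Cole parameters from the Gabriel et al. (1996) parametric survey of tissue dielectric properties, as distributed by the IFAC-CNR database."
}
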