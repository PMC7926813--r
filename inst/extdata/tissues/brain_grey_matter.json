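{
  "name": "brain_grey_matter",
  "label": "Brain grey matter",
  "model": "cole_cole",
  "eps_inf": 4,
  "poles": [
    {
      "delta_eps": 45,
      "tau_s": 7.958e-12,
      "alpha": 0.1
    },
    {
      "delta_eps": 400,
      "tau_s": 1.5915e-08,
      "alpha": 0.15
    },
    {
      "delta_eps": 200000,
      "tau_s": 0.000106103,
      "alpha": 0.22
    },
    {
      "delta_eps": 45000000,
      "tau_s": 0.005305,
      "alpha": 0
    }
  ],
  "sigma_static_s_m": 0.02,
  "provenance": "Four-pole Cole-Cole parameters from the Gabriel et al. (1996) parametric survey of tissue dielectric properties, as distributed by the IFAC-CNR database."
}
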