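{
  "name": "brain_white_matter",
  "label": "Brain white matter",
  "model": "cole_cole",
  "eps_inf": 4,
  "poles": [
    {
      "delta_eps": 32,
      "tau_s": 7.958e-12,
      "alpha": 0.1
    },
    {
      "delta_eps": 100,
      "tau_s": 7.958e-09,
      "alpha": 0.1
    },
    {
      "delta_eps": 40000,
      "tau_s": 5.3052e-05,
      "alpha": 0.3
    },
    {
      "delta_eps": 35000000,
      "tau_s": 0.007958,
      "alpha": 0.02
    }
  ],
  "sigma_static_s_m": 0.02,
  "provenance": "Four-pole Cole-Cole parameters from the Gabriel et al. (1996) parametric survey of tissue dielectric properties, as distributed by the IFAC-CNR database."
}
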