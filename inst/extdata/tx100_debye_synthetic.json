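{
  "name": "tx100",
  "label": "Triton X-100 (pure, 25 C)",
  "model": "debye",
  "eps_static": 7.4,
  "eps_inf": 2.5,
  "tau_s": 2.2e-10,
  "sigma_static_s_m": 0.0,
  "provenance": "Synthetic stand-in Debye parameters for pure Triton X-100 at 25 C. The primary measured fit is not reproduced in the open literature shipped with this package; these values lie in the published range for polyethoxylated surfactants (static permittivity ~7, optical ~2.5, relaxation near 0.7 GHz) and were validated against published 1 GHz dielectric properties of TX-100/saline head-tissue mixtures. Editable: replace with a measured fit if available."
}
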