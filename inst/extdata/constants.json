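{
  "tx100_density_g_ml": 1.07,
  "water_density_g_ml": 0.997,
  "nacl_molar_mass_g_mol": 58.44,
  "abs_plastic": {"eps_real": 3.0, "sigma_s_m": 0.004, "note": "3D-printing ABS wall material at 1 GHz"},
  "provenance": "Bench constants at 25 C from standard physical-chemistry tables; ABS dielectric constants as commonly reported for printed phantom shells at 1 GHz."
}
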