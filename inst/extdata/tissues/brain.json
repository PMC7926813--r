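{
  "name": "brain",
  "label": "Brain (75% white / 25% grey matter blend)",
  "model": "blend",
  "components": [
    {
      "tissue": "brain_white_matter",
      "weight": 0.75
    },
    {
      "tissue": "brain_grey_matter",
      "weight": 0.25
    }
  ],
  "provenance": "Volume-weighted blend of the vendored white- and grey-matter Cole-Cole models; per-frequency linear averaging of the complex permittivity."
}
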