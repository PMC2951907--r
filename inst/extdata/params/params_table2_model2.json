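{
  "formulation": "present",
  "variant": "model2",
  "shared": {
    "alpha": 0.0,
    "nH": 2.65
  },
  "datasets": {
    "heart_ca": { "k0_nmol_mg_s": 0.01972, "K0_uM": 72.8, "tissue": "heart" },
    "liver_ca": { "k0_nmol_mg_s": 0.01775, "K0_uM": 37.9, "tissue": "liver" },
    "liver_dpsi": { "k0_nmol_mg_s": 1.42, "K0_uM": 37.9, "tissue": "liver" }
  }
}
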