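{
  "formulation": "previous",
  "variant": "model1",
  "shared": {
    "alpha": 0.0,
    "beta_e": 0.113,
    "beta_x": 0.887
  },
  "datasets": {
    "heart_ca": { "k0_nmol_mg_s": 0.34, "K0_M": 88.1e-6, "tissue": "heart" },
    "liver_ca": { "k0_nmol_mg_s": 0.30, "K0_M": 45.9e-6, "tissue": "liver" },
    "liver_dpsi": { "k0_nmol_mg_s": 44.5, "K0_M": 45.9e-6, "tissue": "liver" }
  },
  "case2_note": "case2 baseline (m = 1) uses the same values; K_x0 scales by m and k_out0 by m^2 along the non-identifiable family"
}
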