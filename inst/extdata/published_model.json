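{
  "description": "Final vancomycin population PK model for obese adults: typical values, exponential covariate effects on CL (creatinine-based CKD-EPI eGFR in mL/s/1.73 m^2, Boer LBM in kg), SDs of lognormal random effects, additive residual SD.",
  "vd_pop": 75.0,
  "cl_pop": 1.32,
  "beta_cl": { "EGFR": 0.61, "LBM": 0.011 },
  "omega_vd": 0.31,
  "omega_cl": 0.28,
  "sigma_add": 2.9,
  "rse_percent": {
    "vd_pop": 8.66, "cl_pop": 19.3, "beta_cl_LBM": 21.6,
    "beta_cl_EGFR": 11.8, "omega_vd": 16.6, "omega_cl": 9.92, "sigma_add": 20.7
  }
}
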