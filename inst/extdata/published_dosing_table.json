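{
  "description": "Published covariate-based dosing individualization grid for initial vancomycin therapy in obese adults: stratum-specific loading dose (mg) + intermittent maintenance dose (mg) and interval (h). eGFR strata in mL/s/1.73 m^2 (upper-open intervals), LBM split at 70 kg.",
  "egfr_breaks": [0, 0.5, 1, 1.5, 2.13, null],
  "lbm_breaks": [0, 70, null],
  "rows": [
    {"egfr_lo": 0,    "egfr_hi": 0.5,  "lbm_lo": 0,  "lbm_hi": 70,   "ld": 2000, "md": 750,  "interval": 12, "published_pta": 67.5},
    {"egfr_lo": 0,    "egfr_hi": 0.5,  "lbm_lo": 70, "lbm_hi": null, "ld": 2000, "md": 750,  "interval": 8,  "published_pta": 55.0},
    {"egfr_lo": 0.5,  "egfr_hi": 1,    "lbm_lo": 0,  "lbm_hi": 70,   "ld": 2000, "md": 750,  "interval": 8,  "published_pta": 60.9},
    {"egfr_lo": 0.5,  "egfr_hi": 1,    "lbm_lo": 70, "lbm_hi": null, "ld": 2000, "md": 750,  "interval": 8,  "published_pta": 62.2},
    {"egfr_lo": 1,    "egfr_hi": 1.5,  "lbm_lo": 0,  "lbm_hi": 70,   "ld": 2500, "md": 1000, "interval": 8,  "published_pta": 53.6},
    {"egfr_lo": 1,    "egfr_hi": 1.5,  "lbm_lo": 70, "lbm_hi": null, "ld": 2500, "md": 1000, "interval": 8,  "published_pta": 57.5},
    {"egfr_lo": 1.5,  "egfr_hi": 2.13, "lbm_lo": 0,  "lbm_hi": 70,   "ld": 2500, "md": 1250, "interval": 8,  "published_pta": 55.9},
    {"egfr_lo": 1.5,  "egfr_hi": 2.13, "lbm_lo": 70, "lbm_hi": null, "ld": 2500, "md": 1500, "interval": 8,  "published_pta": 58.3},
    {"egfr_lo": 2.13, "egfr_hi": null, "lbm_lo": 0,  "lbm_hi": 70,   "ld": 3000, "md": 1250, "interval": 6,  "published_pta": 59.5},
    {"egfr_lo": 2.13, "egfr_hi": null, "lbm_lo": 70, "lbm_hi": null, "ld": 3000, "md": 1500, "interval": 6,  "published_pta": 57.0}
  ]
}
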