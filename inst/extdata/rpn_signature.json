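{
  "schema_version": 1,
  "mode": "weights_only",
  "hyperparams": {"k_best": 25, "l1_ratio": 0.999, "alpha": 0.005},
  "provenance": {
    "training_label": "published resting-state pain sensitivity network (RPN) signature",
    "note": "21 non-zero partial-correlation weights of the published signature; scaler parameters and intercept were not published, so scores from this fixture are defined up to an affine map"
  },
  "entries": [
    {"label_i": "PO/pSTG", "rsn_i": "VAN+SN+BG+Thal", "atlas_idx_i": 119, "label_j": "pPut",    "rsn_j": "VAN+SN+BG+Thal", "atlas_idx_j": 25,  "weight": 0.270},
    {"label_i": "FP",      "rsn_i": "FPN",            "atlas_idx_i": 75,  "label_j": "5",       "rsn_j": "CER",            "atlas_idx_j": 48,  "weight": 0.245},
    {"label_i": "pCVI",    "rsn_i": "CER",            "atlas_idx_i": 9,   "label_j": "SMC",     "rsn_j": "VAN+SN+BG+Thal", "atlas_idx_j": 28,  "weight": -0.200},
    {"label_i": "R aCrus2","rsn_i": "CER",            "atlas_idx_i": 62,  "label_j": "lPrCG",   "rsn_j": "SMN",            "atlas_idx_j": 93,  "weight": 0.150},
    {"label_i": "dPrCG",   "rsn_i": "SMN",            "atlas_idx_i": 67,  "label_j": "pmVN",    "rsn_j": "VN",             "atlas_idx_j": 51,  "weight": -0.102},
    {"label_i": "pdlVN",   "rsn_i": "VN",             "atlas_idx_i": 43,  "label_j": "mVN",     "rsn_j": "VN",             "atlas_idx_j": 40,  "weight": 0.095},
    {"label_i": "L IPL",   "rsn_i": "DMN",            "atlas_idx_i": 114, "label_j": "mean GM", "rsn_j": "mean GM",        "atlas_idx_j": null,"weight": -0.086},
    {"label_i": "vCaud",   "rsn_i": "VAN+SN+BG+Thal", "atlas_idx_i": 2,   "label_j": "plVN",    "rsn_j": "VN",             "atlas_idx_j": 39,  "weight": 0.085},
    {"label_i": "Acc",     "rsn_i": "MLN",            "atlas_idx_i": 78,  "label_j": "pvmVN",   "rsn_j": "VN",             "atlas_idx_j": 107, "weight": -0.073},
    {"label_i": "CF",      "rsn_i": "MLN",            "atlas_idx_i": 79,  "label_j": "vlPrCG",  "rsn_j": "SMN",            "atlas_idx_j": 110, "weight": -0.062},
    {"label_i": "5",       "rsn_i": "CER",            "atlas_idx_i": 48,  "label_j": "pdlVN",   "rsn_j": "VN",             "atlas_idx_j": 43,  "weight": -0.059},
    {"label_i": "pThal/Hb","rsn_i": "VAN+SN+BG+Thal", "atlas_idx_i": 36,  "label_j": "plVN",    "rsn_j": "VN",             "atlas_idx_j": 39,  "weight": 0.058},
    {"label_i": "dCVI",    "rsn_i": "CER",            "atlas_idx_i": 44,  "label_j": "lOTG",    "rsn_j": "FPN",            "atlas_idx_j": 117, "weight": -0.057},
    {"label_i": "dCiX",    "rsn_i": "CER",            "atlas_idx_i": 11,  "label_j": "L vMFG",  "rsn_j": "FPN",            "atlas_idx_j": 105, "weight": -0.056},
    {"label_i": "R IPS",   "rsn_i": "FPN",            "atlas_idx_i": 20,  "label_j": "plVN",    "rsn_j": "VN",             "atlas_idx_j": 39,  "weight": -0.054},
    {"label_i": "avIns",   "rsn_i": "VAN+SN+BG+Thal", "atlas_idx_i": 12,  "label_j": "admVN",   "rsn_j": "VN",             "atlas_idx_j": 19,  "weight": -0.044},
    {"label_i": "R aMFG",  "rsn_i": "FPN",            "atlas_idx_i": 58,  "label_j": "lPoCG",   "rsn_j": "VAN+SN+BG+Thal", "atlas_idx_j": 102, "weight": 0.043},
    {"label_i": "CrusI",   "rsn_i": "CER",            "atlas_idx_i": 84,  "label_j": "dPoCG",   "rsn_j": "VAN+SN+BG+Thal", "atlas_idx_j": 116, "weight": -0.017},
    {"label_i": "pgACC",   "rsn_i": "DMN",            "atlas_idx_i": 115, "label_j": "mSTG",    "rsn_j": "VAN+SN+BG+Thal", "atlas_idx_j": 88,  "weight": 0.009},
    {"label_i": "Precun",  "rsn_i": "DMN",            "atlas_idx_i": 103, "label_j": "LOG",     "rsn_j": "MLN",            "atlas_idx_j": 109, "weight": -0.003},
    {"label_i": "vThal",   "rsn_i": "VAN+SN+BG+Thal", "atlas_idx_i": 36,  "label_j": "FEF",     "rsn_j": "VAN+SN+BG+Thal", "atlas_idx_j": 113, "weight": -0.001}
  ]
}
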