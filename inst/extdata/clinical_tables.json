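{
  "version": "1.0",
  "note": "Published group summaries for 60 postoperative primary-liver-cancer patients: humanized-nursing experimental arm vs routine-nursing control arm, 30 patients each. Continuous rows are mean/SD in the printed units; 'claim' is the significance bound the source table states; 'printed_p' (baseline rows only) is the P-value printed alongside, kept for reference and never recomputed.",
  "continuous": [
    {"section": "baseline", "label": "age_years", "exp_mean": 47.86, "exp_sd": 2.85, "ctl_mean": 48.38, "ctl_sd": 2.74, "n": 30, "claim": "P>0.05", "printed_p": 0.768},
    {"section": "baseline", "label": "tumor_size_cm", "exp_mean": 6.54, "exp_sd": 1.31, "ctl_mean": 6.87, "ctl_sd": 1.22, "n": 30, "claim": "P>0.05", "printed_p": 0.639},
    {"section": "baseline", "label": "operation_time_h", "exp_mean": 2.94, "exp_sd": 0.76, "ctl_mean": 2.92, "ctl_sd": 0.81, "n": 30, "claim": "P>0.05", "printed_p": 0.727},
    {"section": "acth_pg_ml", "label": "acth_t3", "exp_mean": 41.25, "exp_sd": 3.81, "ctl_mean": 46.21, "ctl_sd": 3.97, "n": 30, "claim": "P<0.05"},
    {"section": "acth_pg_ml", "label": "acth_t4", "exp_mean": 19.55, "exp_sd": 1.72, "ctl_mean": 28.82, "ctl_sd": 2.16, "n": 30, "claim": "P<0.05"},
    {"section": "cortisol_nmol_l", "label": "cortisol_t3", "exp_mean": 424.86, "exp_sd": 16.82, "ctl_mean": 452.42, "ctl_sd": 17.9, "n": 30, "claim": "P<0.05"},
    {"section": "cortisol_nmol_l", "label": "cortisol_t4", "exp_mean": 277.98, "exp_sd": 14.36, "ctl_mean": 309.83, "ctl_sd": 15.72, "n": 30, "claim": "P<0.05"},
    {"section": "cortisol_nmol_l", "label": "cortisol_t5", "exp_mean": 241.53, "exp_sd": 13.27, "ctl_mean": 270.34, "ctl_sd": 13.02, "n": 30, "claim": "P<0.05"},
    {"section": "estradiol_pg_ml", "label": "estradiol_t3", "exp_mean": 53.48, "exp_sd": 11.19, "ctl_mean": 58.77, "ctl_sd": 11.52, "n": 30, "claim": "P<0.05"},
    {"section": "estradiol_pg_ml", "label": "estradiol_t4", "exp_mean": 41.64, "exp_sd": 9.28, "ctl_mean": 47.59, "ctl_sd": 9.31, "n": 30, "claim": "P<0.05"},
    {"section": "estradiol_pg_ml", "label": "estradiol_t5", "exp_mean": 30.59, "exp_sd": 8.16, "ctl_mean": 39.78, "ctl_sd": 8.44, "n": 30, "claim": "P<0.05"},
    {"section": "testosterone_ng_ml", "label": "testosterone_t3", "exp_mean": 2.18, "exp_sd": 1.14, "ctl_mean": 2.65, "ctl_sd": 1.07, "n": 30, "claim": "P<0.05"},
    {"section": "testosterone_ng_ml", "label": "testosterone_t4", "exp_mean": 1.78, "exp_sd": 1.03, "ctl_mean": 2.14, "ctl_sd": 0.98, "n": 30, "claim": "P<0.05"},
    {"section": "testosterone_ng_ml", "label": "testosterone_t5", "exp_mean": 1.42, "exp_sd": 0.69, "ctl_mean": 1.92, "ctl_sd": 0.73, "n": 30, "claim": "P<0.05"},
    {"section": "sas_points", "label": "sas_t3", "exp_mean": 40.24, "exp_sd": 5.81, "ctl_mean": 46.11, "ctl_sd": 5.76, "n": 30, "claim": "P<0.05"},
    {"section": "sas_points", "label": "sas_t4", "exp_mean": 36.55, "exp_sd": 5.02, "ctl_mean": 40.42, "ctl_sd": 4.88, "n": 30, "claim": "P<0.05"},
    {"section": "sas_points", "label": "sas_t5", "exp_mean": 32.53, "exp_sd": 4.8, "ctl_mean": 37.84, "ctl_sd": 4.79, "n": 30, "claim": "P<0.05"},
    {"section": "quality_of_life_points", "label": "qol_physical_function", "exp_mean": 62.59, "exp_sd": 6.82, "ctl_mean": 50.68, "ctl_sd": 6.72, "n": 30, "claim": "P<0.05"},
    {"section": "quality_of_life_points", "label": "qol_self_cognition", "exp_mean": 69.26, "exp_sd": 8.14, "ctl_mean": 61.33, "ctl_sd": 7.29, "n": 30, "claim": "P<0.05"},
    {"section": "quality_of_life_points", "label": "qol_emotional_function", "exp_mean": 73.89, "exp_sd": 6.35, "ctl_mean": 65.38, "ctl_sd": 6.21, "n": 30, "claim": "P<0.05"},
    {"section": "quality_of_life_points", "label": "qol_social_function", "exp_mean": 66.88, "exp_sd": 7.04, "ctl_mean": 60.17, "ctl_sd": 6.26, "n": 30, "claim": "P<0.05"}
  ],
  "counts": [
    {"section": "baseline", "label": "male", "exp_yes": 22, "exp_n": 30, "ctl_yes": 24, "ctl_n": 30, "claim": "P>0.05", "printed_p": 0.744},
    {"section": "baseline", "label": "cirrhosis", "exp_yes": 22, "exp_n": 30, "ctl_yes": 21, "ctl_n": 30, "claim": "P>0.05", "printed_p": 0.692},
    {"section": "compliance", "label": "no_smoking_drinking", "exp_yes": 24, "exp_n": 30, "ctl_yes": 20, "ctl_n": 30, "claim": "P<0.05"},
    {"section": "compliance", "label": "medication_on_time", "exp_yes": 27, "exp_n": 30, "ctl_yes": 24, "ctl_n": 30, "claim": "P<0.05"},
    {"section": "compliance", "label": "diet_control", "exp_yes": 23, "exp_n": 30, "ctl_yes": 18, "ctl_n": 30, "claim": "P<0.05"},
    {"section": "compliance", "label": "self_monitoring", "exp_yes": 21, "exp_n": 30, "ctl_yes": 17, "ctl_n": 30, "claim": "P<0.05"}
  ],
  "lesions": {
    "experimental": {"total": 98, "blood_supply": 92, "necrotic": 6},
    "control": {"total": 95, "blood_supply": 86, "necrotic": 9},
    "claim": "P<0.05"
  }
}
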