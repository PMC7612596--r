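{
  "comment": "Illustrative synthetic-cohort parameters for a 22-patient thoracic FDG-PET test-retest study. Geometric-mean SUVs and wCV magnitudes are typical of published healthy-tissue repeatability ranges; they describe the simulator, not any patient dataset.",
  "n_subjects": 22,
  "organs": [
    {"tissue": "MBP", "metric": "suv_max", "gm_suv": 2.2, "between_sd": 0.15, "wcv_pct": 10.33},
    {"tissue": "MBP", "metric": "suv_mean", "gm_suv": 1.6, "between_sd": 0.15, "wcv_pct": 10.20},
    {"tissue": "MBP", "metric": "suv_peak", "gm_suv": 1.9, "between_sd": 0.15, "wcv_pct": 9.56},
    {"tissue": "LV", "metric": "suv_max", "gm_suv": 4.0, "between_sd": 0.60, "wcv_pct": 69.02},
    {"tissue": "LV", "metric": "suv_mean", "gm_suv": 2.5, "between_sd": 0.60, "wcv_pct": 64.68},
    {"tissue": "LV", "metric": "suv_peak", "gm_suv": 3.2, "between_sd": 0.60, "wcv_pct": 63.63},
    {"tissue": "BM", "metric": "suv_max", "gm_suv": 2.4, "between_sd": 0.20, "wcv_pct": 18.55},
    {"tissue": "BM", "metric": "suv_mean", "gm_suv": 1.8, "between_sd": 0.20, "wcv_pct": 14.85},
    {"tissue": "BM", "metric": "suv_peak", "gm_suv": 2.0, "between_sd": 0.20, "wcv_pct": 11.31},
    {"tissue": "SM_right", "metric": "suv_max", "gm_suv": 1.0, "between_sd": 0.20, "wcv_pct": 23.39},
    {"tissue": "SM_right", "metric": "suv_mean", "gm_suv": 0.55, "between_sd": 0.20, "wcv_pct": 15.45},
    {"tissue": "SM_right", "metric": "suv_peak", "gm_suv": 0.75, "between_sd": 0.20, "wcv_pct": 15.35},
    {"tissue": "SM_left", "metric": "suv_max", "gm_suv": 1.0, "between_sd": 0.20, "wcv_pct": 21.56},
    {"tissue": "SM_left", "metric": "suv_mean", "gm_suv": 0.55, "between_sd": 0.20, "wcv_pct": 15.74},
    {"tissue": "SM_left", "metric": "suv_peak", "gm_suv": 0.75, "between_sd": 0.20, "wcv_pct": 15.15},
    {"tissue": "lung_RUZ", "metric": "suv_max", "gm_suv": 0.85, "between_sd": 0.25, "wcv_pct": 28.24},
    {"tissue": "lung_RUZ", "metric": "suv_mean", "gm_suv": 0.45, "between_sd": 0.25, "wcv_pct": 10.58},
    {"tissue": "lung_RUZ", "metric": "suv_peak", "gm_suv": 0.65, "between_sd": 0.25, "wcv_pct": 27.70},
    {"tissue": "lung_RMZ", "metric": "suv_max", "gm_suv": 0.85, "between_sd": 0.25, "wcv_pct": 25.39},
    {"tissue": "lung_RMZ", "metric": "suv_mean", "gm_suv": 0.45, "between_sd": 0.25, "wcv_pct": 9.85},
    {"tissue": "lung_RMZ", "metric": "suv_peak", "gm_suv": 0.65, "between_sd": 0.25, "wcv_pct": 17.19},
    {"tissue": "lung_RLZ", "metric": "suv_max", "gm_suv": 0.85, "between_sd": 0.25, "wcv_pct": 22.22},
    {"tissue": "lung_RLZ", "metric": "suv_mean", "gm_suv": 0.45, "between_sd": 0.25, "wcv_pct": 10.53},
    {"tissue": "lung_RLZ", "metric": "suv_peak", "gm_suv": 0.65, "between_sd": 0.25, "wcv_pct": 17.80},
    {"tissue": "lung_LUZ", "metric": "suv_max", "gm_suv": 0.85, "between_sd": 0.25, "wcv_pct": 31.27},
    {"tissue": "lung_LUZ", "metric": "suv_mean", "gm_suv": 0.45, "between_sd": 0.25, "wcv_pct": 12.67},
    {"tissue": "lung_LUZ", "metric": "suv_peak", "gm_suv": 0.65, "between_sd": 0.25, "wcv_pct": 19.48},
    {"tissue": "lung_LMZ", "metric": "suv_max", "gm_suv": 0.85, "between_sd": 0.25, "wcv_pct": 16.88},
    {"tissue": "lung_LMZ", "metric": "suv_mean", "gm_suv": 0.45, "between_sd": 0.25, "wcv_pct": 15.10},
    {"tissue": "lung_LMZ", "metric": "suv_peak", "gm_suv": 0.65, "between_sd": 0.25, "wcv_pct": 18.98},
    {"tissue": "lung_LLZ", "metric": "suv_max", "gm_suv": 0.85, "between_sd": 0.25, "wcv_pct": 18.85},
    {"tissue": "lung_LLZ", "metric": "suv_mean", "gm_suv": 0.45, "between_sd": 0.25, "wcv_pct": 18.48},
    {"tissue": "lung_LLZ", "metric": "suv_peak", "gm_suv": 0.65, "between_sd": 0.25, "wcv_pct": 15.40}
  ],
  "observer_jitter": {"suv_max": 0.222, "suv_mean": 0.096, "suv_peak": 0.160},
  "exclusions": [
    {"tissue": "LV", "n": 4, "reason": "outside_fov"},
    {"tissue": "lung_RUZ", "n": 4, "reason": "disease_involvement"},
    {"tissue": "lung_LUZ", "n": 2, "reason": "disease_involvement"},
    {"tissue": "lung_LMZ", "n": 2, "reason": "disease_involvement"},
    {"tissue": "lung_LLZ", "n": 1, "reason": "disease_involvement"}
  ]
}
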