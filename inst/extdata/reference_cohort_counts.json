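{
  "description": "Published summary counts from a large multisite retrospective ED cohort of adult encounters with urinalysis and urine culture, used as a worked-example fixture for the package's metric operations. Counts only; no row-level data.",
  "n_encounters": 149449,
  "n_culture_positive": 22521,
  "n_strict_uti": 20080,
  "n_no_uti": 129369,
  "physician_true_positive": 12735,
  "physician_false_positive": 11807,
  "physician_false_negative": 7345,
  "physician_diagnosed_total": 24542,
  "physician_diagnosed_explicit": 22574,
  "cv_points": {
    "model_accuracy": 0.039,
    "model_dor": 0.48,
    "physician_accuracy": 0.080,
    "physician_dor": 0.33
  },
  "n_intersectional_groups": 19
}
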