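{
  "model_name": "fsrs-default-synthetic",
  "sex_specific": {
    "male": {
      "betas": {
        "age": 0.0505,
        "sbp": 0.014,
        "antihypertensive_treatment": 0.3263,
        "diabetes": 0.3384,
        "current_smoker": 0.5147,
        "cvd_history": 0.5212,
        "atrial_fibrillation": 0.6089,
        "lvh": 0.846
      },
      "covariate_means": {
        "age": 65.0,
        "sbp": 136.0,
        "antihypertensive_treatment": 0.22,
        "diabetes": 0.08,
        "current_smoker": 0.25,
        "cvd_history": 0.15,
        "atrial_fibrillation": 0.03,
        "lvh": 0.04
      },
      "baseline_survival": { "5": 0.957, "10": 0.9 },
      "provenance": "SYNTHETIC STAND-IN. Framingham-style magnitudes chosen to yield plausible 5/10-year absolute stroke risks for exercising the scoring engine; not a verified transcription of any published coefficient table. Supply your own coefficient file for substantive use."
    },
    "female": {
      "betas": {
        "age": 0.0665,
        "sbp": 0.0118,
        "antihypertensive_treatment": 0.2731,
        "diabetes": 0.3086,
        "current_smoker": 0.5419,
        "cvd_history": 0.4477,
        "atrial_fibrillation": 0.8953,
        "lvh": 0.7735
      },
      "covariate_means": {
        "age": 66.0,
        "sbp": 137.0,
        "antihypertensive_treatment": 0.25,
        "diabetes": 0.07,
        "current_smoker": 0.2,
        "cvd_history": 0.1,
        "atrial_fibrillation": 0.03,
        "lvh": 0.03
      },
      "baseline_survival": { "5": 0.973, "10": 0.94 },
      "provenance": "SYNTHETIC STAND-IN. See male block."
    }
  }
}
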