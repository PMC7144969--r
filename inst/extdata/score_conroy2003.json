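{
  "comment": "SCORE 10-year fatal cardiovascular risk equations (total-cholesterol version). Two cause-specific Weibull models per sex (coronary heart disease; non-coronary cardiovascular disease), combined here with the corrected product rule 1-(1-R_chd)*(1-R_nonchd). Coefficients transcribed from the SCORE development publication: Conroy RM et al., Estimation of ten-year risk of fatal cardiovascular disease in Europe: the SCORE project. Eur Heart J 2003;24:987-1003 (coefficient tables for high- and low-risk regions).",
  "equations": [
    {
      "name": "SCORE-H",
      "family": "score_weibull_two_cause",
      "region": "high",
      "horizon_years": 10,
      "combination_rule": "corrected_product",
      "provenance": "Conroy et al. 2003, Eur Heart J 24:987-1003, high-risk-region coefficient table (CHD and non-CHD CVD Weibull models, total-cholesterol version)",
      "sexes": {
        "male": {
          "chd": {
            "alpha": -21.0, "p": 4.62, "age_origin": 20,
            "betas": {"total_chol": 0.24, "sbp": 0.018, "smoker": 0.71},
            "centering": {"total_chol": 6, "sbp": 120, "smoker": 0}
          },
          "non_chd_cvd": {
            "alpha": -25.7, "p": 5.47, "age_origin": 20,
            "betas": {"total_chol": 0.02, "sbp": 0.022, "smoker": 0.63},
            "centering": {"total_chol": 6, "sbp": 120, "smoker": 0}
          }
        },
        "female": {
          "chd": {
            "alpha": -28.7, "p": 6.23, "age_origin": 20,
            "betas": {"total_chol": 0.24, "sbp": 0.018, "smoker": 0.71},
            "centering": {"total_chol": 6, "sbp": 120, "smoker": 0}
          },
          "non_chd_cvd": {
            "alpha": -30.0, "p": 6.42, "age_origin": 20,
            "betas": {"total_chol": 0.02, "sbp": 0.022, "smoker": 0.63},
            "centering": {"total_chol": 6, "sbp": 120, "smoker": 0}
          }
        }
      }
    },
    {
      "name": "SCORE-L",
      "family": "score_weibull_two_cause",
      "region": "low",
      "horizon_years": 10,
      "combination_rule": "corrected_product",
      "provenance": "Conroy et al. 2003, Eur Heart J 24:987-1003, low-risk-region coefficient table (CHD and non-CHD CVD Weibull models, total-cholesterol version)",
      "sexes": {
        "male": {
          "chd": {
            "alpha": -22.1, "p": 4.71, "age_origin": 20,
            "betas": {"total_chol": 0.24, "sbp": 0.018, "smoker": 0.71},
            "centering": {"total_chol": 6, "sbp": 120, "smoker": 0}
          },
          "non_chd_cvd": {
            "alpha": -26.7, "p": 5.64, "age_origin": 20,
            "betas": {"total_chol": 0.02, "sbp": 0.022, "smoker": 0.63},
            "centering": {"total_chol": 6, "sbp": 120, "smoker": 0}
          }
        },
        "female": {
          "chd": {
            "alpha": -29.8, "p": 6.36, "age_origin": 20,
            "betas": {"total_chol": 0.24, "sbp": 0.018, "smoker": 0.71},
            "centering": {"total_chol": 6, "sbp": 120, "smoker": 0}
          },
          "non_chd_cvd": {
            "alpha": -31.0, "p": 6.62, "age_origin": 20,
            "betas": {"total_chol": 0.02, "sbp": 0.022, "smoker": 0.63},
            "centering": {"total_chol": 6, "sbp": 120, "smoker": 0}
          }
        }
      }
    }
  ]
}
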