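{
  "comment": "SYNTHETIC stand-in coefficients for the SCORE OP (Older Persons) equations. These are NOT the published SCORE OP values: they are illustrative coefficients of realistic sign and magnitude for persons aged 70+, chosen once so that the linear-predictor-on-baseline-survival engine produces risks of the right order. For any real validation against SCORE OP, replace this file with a registry transcribed from the development publication (Cooney MT et al., Cardiovascular risk estimation in older persons: SCORE O.P., Eur J Prev Cardiol 2016;23:1093-1103) and cite the exact source table in the provenance strings.",
  "equations": [
    {
      "name": "SCORE OP-H",
      "family": "score_op_linear_predictor",
      "region": "high",
      "horizon_years": 10,
      "provenance": "SYNTHETIC stand-in, not the published SCORE O.P. high-risk-region coefficients; replace with a transcription from Cooney et al. 2016, Eur J Prev Cardiol 23:1093-1103",
      "sexes": {
        "male": {
          "baseline_survival": {"5": 0.89, "10": 0.72},
          "betas": {"age": 0.085, "total_chol": 0.10, "hdl_chol": -0.45, "sbp": 0.011, "smoker": 0.35, "diabetes": 0.52},
          "centering": {"age": 75, "total_chol": 5.5, "hdl_chol": 1.4, "sbp": 145, "smoker": 0, "diabetes": 0}
        },
        "female": {
          "baseline_survival": {"5": 0.90, "10": 0.74},
          "betas": {"age": 0.085, "total_chol": 0.10, "hdl_chol": -0.45, "sbp": 0.011, "smoker": 0.35, "diabetes": 0.52},
          "centering": {"age": 75, "total_chol": 5.5, "hdl_chol": 1.4, "sbp": 145, "smoker": 0, "diabetes": 0}
        }
      }
    },
    {
      "name": "SCORE OP-L",
      "family": "score_op_linear_predictor",
      "region": "low",
      "horizon_years": 10,
      "provenance": "SYNTHETIC stand-in, not the published SCORE O.P. low-risk-region coefficients; replace with a transcription from Cooney et al. 2016, Eur J Prev Cardiol 23:1093-1103",
      "sexes": {
        "male": {
          "baseline_survival": {"5": 0.92, "10": 0.79},
          "betas": {"age": 0.085, "total_chol": 0.10, "hdl_chol": -0.45, "sbp": 0.011, "smoker": 0.35, "diabetes": 0.52},
          "centering": {"age": 75, "total_chol": 5.5, "hdl_chol": 1.4, "sbp": 145, "smoker": 0, "diabetes": 0}
        },
        "female": {
          "baseline_survival": {"5": 0.93, "10": 0.81},
          "betas": {"age": 0.085, "total_chol": 0.10, "hdl_chol": -0.45, "sbp": 0.011, "smoker": 0.35, "diabetes": 0.52},
          "centering": {"age": 75, "total_chol": 5.5, "hdl_chol": 1.4, "sbp": 145, "smoker": 0, "diabetes": 0}
        }
      }
    },
    {
      "name": "SCORE OP-H 5y",
      "family": "score_op_linear_predictor",
      "region": "high",
      "horizon_years": 5,
      "provenance": "SYNTHETIC stand-in, not the published SCORE O.P. high-risk-region 5-year coefficients; replace with a transcription from Cooney et al. 2016, Eur J Prev Cardiol 23:1093-1103",
      "sexes": {
        "male": {
          "baseline_survival": {"5": 0.89, "10": 0.72},
          "betas": {"age": 0.085, "total_chol": 0.10, "hdl_chol": -0.45, "sbp": 0.011, "smoker": 0.35, "diabetes": 0.52},
          "centering": {"age": 75, "total_chol": 5.5, "hdl_chol": 1.4, "sbp": 145, "smoker": 0, "diabetes": 0}
        },
        "female": {
          "baseline_survival": {"5": 0.90, "10": 0.74},
          "betas": {"age": 0.085, "total_chol": 0.10, "hdl_chol": -0.45, "sbp": 0.011, "smoker": 0.35, "diabetes": 0.52},
          "centering": {"age": 75, "total_chol": 5.5, "hdl_chol": 1.4, "sbp": 145, "smoker": 0, "diabetes": 0}
        }
      }
    },
    {
      "name": "SCORE OP-L 5y",
      "family": "score_op_linear_predictor",
      "region": "low",
      "horizon_years": 5,
      "provenance": "SYNTHETIC stand-in, not the published SCORE O.P. low-risk-region 5-year coefficients; replace with a transcription from Cooney et al. 2016, Eur J Prev Cardiol 23:1093-1103",
      "sexes": {
        "male": {
          "baseline_survival": {"5": 0.92, "10": 0.79},
          "betas": {"age": 0.085, "total_chol": 0.10, "hdl_chol": -0.45, "sbp": 0.011, "smoker": 0.35, "diabetes": 0.52},
          "centering": {"age": 75, "total_chol": 5.5, "hdl_chol": 1.4, "sbp": 145, "smoker": 0, "diabetes": 0}
        },
        "female": {
          "baseline_survival": {"5": 0.93, "10": 0.81},
          "betas": {"age": 0.085, "total_chol": 0.10, "hdl_chol": -0.45, "sbp": 0.011, "smoker": 0.35, "diabetes": 0.52},
          "centering": {"age": 75, "total_chol": 5.5, "hdl_chol": 1.4, "sbp": 145, "smoker": 0, "diabetes": 0}
        }
      }
    }
  ]
}
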