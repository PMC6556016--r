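{
  "spec_version": "1",
  "model_id": "example_axillary_logistic",
  "family": "logistic",
  "outcome_label": "axillary lymph node metastasis",
  "horizons": [
    1
  ],
  "covariates": [
    {
      "name": "node_diameter",
      "kind": "continuous",
      "center": 10,
      "dev_summary": {
        "mean": 12,
        "sd": 5
      }
    },
    {
      "name": "cortical_thickness",
      "kind": "continuous",
      "center": 3,
      "dev_summary": {
        "mean": 3.5,
        "sd": 1.2
      }
    },
    {
      "name": "hilum",
      "kind": "categorical",
      "levels": [
        "present",
        "absent"
      ],
      "reference_level": "present",
      "unknown_weights": {
        "present": 0.7,
        "absent": 0.3
      },
      "dev_summary": {
        "frequencies": {
          "present": 0.7,
          "absent": 0.3
        }
      }
    },
    {
      "name": "grade",
      "kind": "categorical",
      "levels": [
        "I",
        "II",
        "III"
      ],
      "reference_level": "I",
      "unknown_weights": {
        "I": 0.3,
        "II": 0.5,
        "III": 0.2
      },
      "dev_summary": {
        "frequencies": {
          "I": 0.3,
          "II": 0.5,
          "III": 0.2
        }
      }
    },
    {
      "name": "tumor_size",
      "kind": "continuous",
      "center": 20,
      "dev_summary": {
        "mean": 22,
        "sd": 8
      }
    },
    {
      "name": "er_status",
      "kind": "categorical",
      "levels": [
        "positive",
        "negative"
      ],
      "reference_level": "positive",
      "unknown_weights": {
        "positive": 0.75,
        "negative": 0.25
      },
      "dev_summary": {
        "frequencies": {
          "positive": 0.75,
          "negative": 0.25
        }
      }
    }
  ],
  "intercept": -2.4,
  "coefficients": {
    "node_diameter": 0.08,
    "cortical_thickness": 0.35,
    "hilum": {
      "absent": 0.9
    },
    "grade": {
      "II": 0.4,
      "III": 0.8
    },
    "tumor_size": 0.03,
    "er_status": {
      "negative": 0.3
    }
  }
}
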