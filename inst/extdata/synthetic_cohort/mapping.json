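{
  "covariates": {
    "node_diameter": {
      "column": "node_diameter_src",
      "scale": 1,
      "missing_codes": [
        ""
      ]
    },
    "cortical_thickness": {
      "column": "cortical_thickness_src",
      "scale": 1,
      "missing_codes": [
        ""
      ]
    },
    "hilum": {
      "column": "hilum_src",
      "value_map": {
        "1": "present",
        "2": "absent"
      },
      "missing_codes": [
        ""
      ]
    },
    "grade": {
      "column": "grade_src",
      "value_map": {
        "1": "I",
        "2": "II",
        "3": "III"
      },
      "missing_codes": [
        ""
      ]
    },
    "tumor_size": {
      "column": "tumor_size_src",
      "scale": 1,
      "missing_codes": [
        ""
      ]
    },
    "er_status": {
      "column": "er_status_src",
      "value_map": {
        "1": "positive",
        "2": "negative"
      },
      "missing_codes": [
        ""
      ]
    }
  },
  "outcome": {
    "column": "outcome_src",
    "event_code": "1",
    "nonevent_code": "0",
    "missing_codes": [
      ""
    ]
  }
}
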