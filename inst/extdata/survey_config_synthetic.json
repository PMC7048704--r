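{
  "comment": "Synthetic survey configuration emulating a 2016 DHS-like round.",
  "n_households": 5000,
  "seed": 20160101,
  "year": 2016,
  "residence_split": 0.6,
  "education_split": 0.65,
  "coverage_spec": {
    "fp_need_satisfied": [58, 61, 64, 67, 70],
    "anc_skilled": [74, 82, 87, 91, 96],
    "sba": [42, 52, 63, 74, 86],
    "td2plus": [58, 62, 65, 68, 72],
    "bcg": [96, 97, 98, 99, 100],
    "dpt3": [80, 84, 86, 88, 92],
    "polio3": [78, 82, 85, 88, 92],
    "msl": [84, 88, 90, 92, 96],
    "ort": [52, 57, 61, 66, 71],
    "cpnm": [74, 81, 85, 89, 95],
    "vitamin_a": [80, 82, 83, 84, 86],
    "water_improved": [90, 93, 95, 97, 99]
  }
}
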