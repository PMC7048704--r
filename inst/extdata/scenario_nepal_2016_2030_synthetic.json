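{
  "comment": "Synthetic illustrative lives-saved scenario for Nepal-like demography. Baseline mortality rates are published national figures (stillbirth 18/1000, NMR 21/1000, post-neonatal under-five 17/1000, MMR 239/100000); cause structure, effectiveness and affected fractions are illustrative, not a country database.",
  "base_year": 2016,
  "target_year": 2030,
  "births_per_year": 570000,
  "birth_growth": 0,
  "groups": {
    "maternal": {
      "rate": 239,
      "per": 100000,
      "causes": {
        "haemorrhage": 0.3,
        "hypertensive": 0.2,
        "sepsis": 0.15,
        "other": 0.35
      },
      "interventions": [
        {
          "name": "skilled_birth_attendance",
          "effectiveness": {
            "haemorrhage": 0.6,
            "hypertensive": 0.5,
            "sepsis": 0.55
          },
          "affected_fraction": 0.9,
          "baseline": 63,
          "scaleup": [63, 70.37, 78.6, 87.8, 98.07, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100]
        },
        {
          "name": "anc_skilled",
          "effectiveness": {
            "hypertensive": 0.3,
            "sepsis": 0.2
          },
          "affected_fraction": 0.8,
          "baseline": 86,
          "scaleup": [86, 92.62, 99.75, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100]
        }
      ]
    },
    "stillbirth": {
      "rate": 18,
      "per": 1000,
      "causes": {
        "intrapartum": 0.4,
        "antepartum": 0.6
      },
      "interventions": [
        {
          "name": "skilled_birth_attendance",
          "effectiveness": {
            "intrapartum": 0.45
          },
          "affected_fraction": 0.85,
          "baseline": 63,
          "scaleup": [63, 70.37, 78.6, 87.8, 98.07, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100]
        },
        {
          "name": "anc_skilled",
          "effectiveness": {
            "antepartum": 0.25
          },
          "affected_fraction": 0.8,
          "baseline": 86,
          "scaleup": [86, 92.62, 99.75, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100]
        }
      ]
    },
    "neonatal": {
      "rate": 21,
      "per": 1000,
      "causes": {
        "prematurity": 0.3,
        "asphyxia": 0.25,
        "sepsis": 0.25,
        "tetanus": 0.05,
        "other": 0.15
      },
      "interventions": [
        {
          "name": "skilled_birth_attendance",
          "effectiveness": {
            "asphyxia": 0.4,
            "sepsis": 0.25
          },
          "affected_fraction": 0.9,
          "baseline": 63,
          "scaleup": [63, 70.37, 78.6, 87.8, 98.07, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100]
        },
        {
          "name": "anc_skilled",
          "effectiveness": {
            "prematurity": 0.2
          },
          "affected_fraction": 0.8,
          "baseline": 86,
          "scaleup": [86, 92.62, 99.75, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100]
        },
        {
          "name": "tetanus_toxoid",
          "effectiveness": {
            "tetanus": 0.85
          },
          "affected_fraction": 0.9,
          "baseline": 65,
          "scaleup": [65, 66.56, 68.16, 69.79, 71.47, 73.18, 74.94, 76.74, 78.58, 80.47, 82.4, 84.37, 86.4, 88.47, 90.6]
        }
      ]
    },
    "postneonatal_under5": {
      "rate": 17,
      "per": 1000,
      "causes": {
        "pneumonia": 0.35,
        "diarrhoea": 0.3,
        "measles": 0.1,
        "other": 0.25
      },
      "interventions": [
        {
          "name": "care_seeking_pneumonia",
          "effectiveness": {
            "pneumonia": 0.7
          },
          "affected_fraction": 0.8,
          "baseline": 84.9,
          "scaleup": [84.9, 91.86, 99.39, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100, 100]
        },
        {
          "name": "ort_continued_feeding",
          "effectiveness": {
            "diarrhoea": 0.65
          },
          "affected_fraction": 0.85,
          "baseline": 61.4,
          "scaleup": [61.4, 62.93, 64.51, 66.12, 67.77, 69.47, 71.21, 72.99, 74.81, 76.68, 78.6, 80.56, 82.58, 84.64, 86.76]
        },
        {
          "name": "measles_rubella_vaccination",
          "effectiveness": {
            "measles": 0.85
          },
          "affected_fraction": 0.95,
          "baseline": 90,
          "scaleup": [90, 91.53, 93.09, 94.67, 96.28, 97.91, 99.58, 100, 100, 100, 100, 100, 100, 100, 100]
        }
      ]
    }
  }
}
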