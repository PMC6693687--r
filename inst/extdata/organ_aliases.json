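{
  "impact": {
    "labels": {
      "stomach": "stomach",
      "colon": "colon",
      "upper large intestine": "colon",
      "lower large intestine": "colon",
      "liver": "liver",
      "lung": "lung",
      "lungs": "lung",
      "prostate": "prostate",
      "uterus": "uterus",
      "ovaries": "ovary",
      "ovary": "ovary",
      "breast": "breast",
      "breasts": "breast",
      "bladder": "bladder",
      "urinary bladder": "bladder",
      "thyroid": "thyroid",
      "bone marrow": "leukaemia",
      "red bone marrow": "leukaemia"
    },
    "remainder_organs": [
      "adrenals",
      "extrathoracic region",
      "gall bladder",
      "heart",
      "kidneys",
      "lymph nodes",
      "muscle",
      "oral mucosa",
      "oesophagus",
      "pancreas",
      "small intestine",
      "spleen",
      "thymus"
    ]
  },
  "ncict": {
    "labels": {
      "stomach": "stomach",
      "stomach wall": "stomach",
      "colon": "colon",
      "colon wall": "colon",
      "liver": "liver",
      "lung": "lung",
      "lungs": "lung",
      "prostate": "prostate",
      "uterus": "uterus",
      "ovaries": "ovary",
      "ovary": "ovary",
      "breast": "breast",
      "breasts": "breast",
      "bladder": "bladder",
      "urinary bladder": "bladder",
      "thyroid": "thyroid",
      "active marrow": "leukaemia"
    },
    "remainder_organs": [
      "adrenals",
      "extrathoracic region",
      "gall bladder",
      "heart",
      "kidneys",
      "lymph nodes",
      "muscle",
      "oral mucosa",
      "oesophagus",
      "pancreas",
      "small intestine",
      "spleen",
      "thymus"
    ]
  }
}
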