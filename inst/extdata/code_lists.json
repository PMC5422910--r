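[
  {
    "name": "crs_icd10",
    "system": "ICD10",
    "codes": ["J32", "J32.0", "J32.1", "J32.2", "J32.3", "J32.4", "J32.8", "J32.9", "J33", "J33.0", "J33.1", "J33.8", "J33.9"]
  },
  {
    "name": "crs_icd9",
    "system": "ICD9",
    "codes": ["473", "473.0", "473.1", "473.2", "473.3", "473.8", "473.9", "471", "471.0", "471.1", "471.8", "471.9"]
  },
  {
    "name": "ess_cci",
    "system": "CCI",
    "codes": ["1.EU.^^.^^", "1.EU.52.^^", "1.EU.87.^^", "1.EV.^^.^^", "1.EV.52.^^", "1.EV.87.^^", "1.EW.^^.^^", "1.EW.52.^^", "1.EX.^^", "1.EX.52.^^", "1.EX.59.^^", "1.EX.80.^^", "1.EX.87.^^", "1.EY.^^.^^", "1.EY.87.^^", "1.EY.91.^^"]
  }
]
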