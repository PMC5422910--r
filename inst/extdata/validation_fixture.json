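{
  "year_label": "2013",
  "cases": {
    "both": 186,
    "dx_only": 2,
    "proc_only": 0,
    "neither": 0
  },
  "controls": {
    "both": 6,
    "dx_only": 0,
    "proc_only": 0,
    "neither": 198
  }
}
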