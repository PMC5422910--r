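{
  "year_label": "2011-2012",
  "cases": {
    "both": 333,
    "dx_only": 2,
    "proc_only": 3,
    "neither": 9
  },
  "controls": {
    "both": 16,
    "dx_only": 8,
    "proc_only": 8,
    "neither": 184975
  }
}
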