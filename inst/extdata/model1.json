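{
  "name": "model1",
  "combiner": "ANY",
  "clauses": [
    {
      "field": "dx",
      "code_list": "crs_icd10"
    }
  ]
}
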