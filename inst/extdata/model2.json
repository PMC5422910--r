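{
  "name": "model2",
  "combiner": "ANY",
  "clauses": [
    {
      "field": "proc",
      "code_list": "ess_cci"
    }
  ]
}
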