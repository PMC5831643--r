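{
  "forced_investments": [20, 20, null, null, null, null, null, null, null, null],
  "forced_repayments": [30, 10, null, null, null, null, null, null, null, null],
  "description": "scripted cooperation then subpar repayment"
}
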