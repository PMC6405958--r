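{
  "model1b": ["attachment", "omad2_decay"],
  "model2b": ["attachment"],
  "model3b": ["attachment"]
}
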