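{
  "A1": {"tissue": "immune", "cell_class": "T"},
  "A2": {"tissue": "immune", "cell_class": "T"},
  "B1": {"tissue": "stroma", "cell_class": "fibroblast"},
  "B2": {"tissue": "stroma", "cell_class": "fibroblast"}
}
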