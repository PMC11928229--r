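{
  "state": "{pre} {entity} {degree} {value} {post} {certainty}",
  "state_separator": " or ",
  "sentence_separator": "; ",
  "group_format": "{tab}: {sentences}."
}
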