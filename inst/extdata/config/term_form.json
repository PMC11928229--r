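{
  "prepositions": ["in", "on", "at", "of", "with", "under", "over",
                   "along", "between", "within", "above", "below",
                   "beneath", "near"],
  "conjunctions": ["and", "or", "and/or"],
  "plural_exceptions": ["axis", "basis", "species", "genus", "ramus",
                        "sinus", "apex", "calamus", "mucronulatus"],
  "singular_suffixes": ["ous", "us", "is", "ss", "ics"]
}
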