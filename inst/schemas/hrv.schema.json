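{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "HRV reports: reference series plus one entry per template label",
  "type": "object",
  "required": ["reference"],
  "properties": {
    "reference": {"type": "object"},
    "S1": {"type": "object"},
    "S2": {"type": "object"},
    "S1S2": {"type": "object"}
  }
}
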