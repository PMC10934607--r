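{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Recognition statistics and paired inter-beat intervals per label",
  "type": "object",
  "required": [],
  "properties": {
    "S1": {"type": "object"},
    "S2": {"type": "object"},
    "S1S2": {"type": "object"}
  },
  "definitions": {
    "label_stats": {
      "type": "object",
      "required": ["tp", "fp", "fn", "sensitivity", "ppv", "n_intervals",
                   "intervals_ref_ms", "intervals_det_ms"]
    }
  }
}
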