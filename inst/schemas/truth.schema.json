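{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Ground-truth beat timings of a synthetic recording (seconds)",
  "type": "object",
  "required": ["r_times", "s1_times", "s2_times"],
  "properties": {
    "r_times": {"type": "array", "items": {"type": "number"}},
    "s1_times": {"type": "array", "items": {"type": "number"}},
    "s2_times": {"type": "array", "items": {"type": "number"}}
  }
}
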