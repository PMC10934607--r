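{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Detected R-peak times (seconds)",
  "type": "object",
  "required": ["times"],
  "properties": {
    "times": {"type": "array", "items": {"type": "number"}}
  }
}
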