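{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Passing-Bablok / correlation / Bland-Altman agreement per label",
  "type": "object",
  "required": [],
  "properties": {
    "S1": {"type": "object"},
    "S2": {"type": "object"},
    "S1S2": {"type": "object"}
  },
  "definitions": {
    "label_agreement": {
      "type": "object",
      "required": ["n", "r", "r_ci", "slope", "slope_ci", "intercept",
                   "intercept_ci", "cusum_linear", "bias", "bias_ci",
                   "loa", "normal_differences"]
    }
  }
}
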