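{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Single HRV index report",
  "type": "object",
  "required": ["mean_rr", "sdnn", "mean_hr", "sd_hr", "min_hr", "max_hr",
               "rmssd", "nn50", "pnn50", "lf_abs", "hf_abs", "total_power",
               "lf_rel", "hf_rel", "lf_nu", "hf_nu", "lf_hf",
               "sd1", "sd2", "sd2_sd1", "apen", "sampen",
               "dfa_a1", "dfa_a2"]
}
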