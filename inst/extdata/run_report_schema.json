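{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "flcsig run report",
  "type": "object",
  "required": ["version", "seed", "parameters", "samples"],
  "properties": {
    "version": { "type": "string" },
    "seed": { "type": "integer" },
    "parameters": { "type": "object" },
    "samples": { "type": "object" },
    "fusion": { "type": "object" },
    "cnv_calls": { "type": "object" },
    "de_counts": { "type": "object" },
    "concordant": { "type": "object" },
    "clade": { "type": "object" },
    "separation": { "type": "object" },
    "signature_eval": { "type": "object" }
  }
}
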