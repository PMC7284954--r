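{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "phragpath pipeline summary",
  "type": "object",
  "required": ["meta"],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["package", "version", "seed", "alpha", "n_permutations", "thresholds"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": "number"},
        "alpha": {"type": "number"},
        "n_permutations": {"type": "number"},
        "thresholds": {"type": "object"}
      }
    },
    "seedling": {"type": "object"},
    "mature": {"type": "object"},
    "saprophyte": {"type": "object"},
    "trophic_experimental": {"type": "object"},
    "literature": {"type": "object"}
  }
}
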