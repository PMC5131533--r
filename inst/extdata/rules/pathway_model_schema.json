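{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "PathwayModel",
  "description": "Monotone OR-of-AND pathway-completeness rule: phenotype is POSITIVE when at least one route is satisfied; a route is satisfied when every isoform group contains at least one functional gene.",
  "type": "object",
  "required": ["sugar", "routes"],
  "properties": {
    "sugar": { "type": "string", "minLength": 1 },
    "name": { "type": "string" },
    "routes": {
      "type": "array",
      "items": {
        "type": "array",
        "items": {
          "type": "array",
          "items": { "type": "string", "minLength": 1 },
          "minItems": 1
        }
      }
    }
  }
}
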