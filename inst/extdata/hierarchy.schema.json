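{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "taxagree label hierarchy document",
  "type": "array",
  "items": {
    "type": "object",
    "required": ["id", "name", "category"],
    "properties": {
      "id": {"type": "string", "pattern": "^[a-z][a-z0-9_]*$"},
      "name": {"type": "string"},
      "parent": {"type": "string", "description": "absent for a category root"},
      "category": {"type": "string"},
      "reconstructed": {"type": "boolean", "default": false}
    },
    "additionalProperties": false
  }
}
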