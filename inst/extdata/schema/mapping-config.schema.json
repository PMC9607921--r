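{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "urn:ehr13606:mapping-config:1",
  "title": "Terminology mapping config",
  "description": "Local app literal to SNOMED CT binding table driving the conversion module. Section keys are the local labels as stored by the app (e.g. Spanish literals); labels are compared case-insensitively after accent folding and trimming.",
  "type": "object",
  "required": ["scheme_uri", "findings", "severities"],
  "properties": {
    "scheme_uri": { "type": "string", "minLength": 1 },
    "note": { "type": "string" },
    "findings": { "$ref": "#/$defs/section" },
    "severities": { "$ref": "#/$defs/section" }
  },
  "additionalProperties": false,
  "$defs": {
    "section": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["concept_id", "display"],
        "properties": {
          "concept_id": { "type": "string", "pattern": "^[0-9]+$" },
          "display": { "type": "string", "minLength": 1 },
          "code_uri": { "type": "string", "minLength": 1 }
        },
        "additionalProperties": false
      }
    }
  }
}
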