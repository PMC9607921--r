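{
  "archetype_id": "side_effect",
  "concept": "Side effect",
  "ontology_class": "Secondary_effect",
  "constraints": [
    { "name": "date", "value_kind": "date", "required": true },
    { "name": "finding", "value_kind": "coded", "required": true, "binding": "findings" },
    { "name": "value", "value_kind": "text", "required": false },
    { "name": "severity", "value_kind": "coded", "required": true, "binding": "severities" }
  ]
}
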