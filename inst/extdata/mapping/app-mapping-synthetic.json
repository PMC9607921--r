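{
  "scheme_uri": "http://snomed.info/sct",
  "note": "Synthetic demonstration mapping. Only 'Vigilia'/'Wakefulness' (365930002) and the three severity qualifiers (255604002, 6736007, 24484000) are real SNOMED CT international-edition codes; every concept_id starting with 9 is a placeholder and must not be read as real SNOMED CT content.",
  "findings": {
    "Vigilia": { "concept_id": "365930002", "display": "Wakefulness" },
    "Náusea": { "concept_id": "900000101", "display": "Nausea (synthetic code)" },
    "Vómitos": { "concept_id": "900000102", "display": "Vomiting (synthetic code)" },
    "Fatiga": { "concept_id": "900000103", "display": "Fatigue (synthetic code)" },
    "Cefalea": { "concept_id": "900000104", "display": "Headache (synthetic code)" },
    "Diarrea": { "concept_id": "900000105", "display": "Diarrhea (synthetic code)" },
    "Estreñimiento": { "concept_id": "900000106", "display": "Constipation (synthetic code)" },
    "Fiebre": { "concept_id": "900000107", "display": "Fever (synthetic code)" },
    "Mareo": { "concept_id": "900000108", "display": "Dizziness (synthetic code)" },
    "Dolor articular": { "concept_id": "900000109", "display": "Joint pain (synthetic code)" },
    "Pérdida de apetito": { "concept_id": "900000110", "display": "Loss of appetite (synthetic code)" },
    "Caída del cabello": { "concept_id": "900000111", "display": "Hair loss (synthetic code)" }
  },
  "severities": {
    "Leve": { "concept_id": "255604002", "display": "Mild" },
    "Moderado": { "concept_id": "6736007", "display": "Moderate" },
    "Severo": { "concept_id": "24484000", "display": "Severe" }
  }
}
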