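{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Sample metadata document for a fixed-target serial run",
  "description": "Second of the two per-run JSON documents. 'cell' and 'symmetry' are interpreted by the pipeline (they seed cell averaging and asymmetric-unit mapping); the remaining fields are provenance for the downstream structure-determination steps. Artifact-defined superset schema.",
  "type": "object",
  "properties": {
    "cell": {
      "type": "array",
      "description": "a, b, c in Angstrom then alpha, beta, gamma in degrees",
      "items": {"type": "number"},
      "minItems": 6,
      "maxItems": 6
    },
    "symmetry": {"type": "string", "description": "Hermann-Mauguin space-group symbol"},
    "protein": {"type": "string"},
    "pdb_model": {"type": "string", "description": "reference model for molecular replacement"},
    "intent": {"type": "string"},
    "principal_investigator": {"type": "string"}
  },
  "required": ["cell", "symmetry"]
}
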