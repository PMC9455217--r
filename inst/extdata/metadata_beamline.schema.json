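{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Beamline metadata document for a fixed-target serial run",
  "description": "One of the two JSON documents written per collection run. All fields are carried through as provenance; none are interpreted by the merging pipeline. This schema is artifact-defined: it is a documented superset of the fields a beamline control GUI records.",
  "type": "object",
  "properties": {
    "wavelength_A": {"type": "number", "exclusiveMinimum": 0},
    "beam_um": {"type": "array", "items": {"type": "number"}, "minItems": 2, "maxItems": 2},
    "step_um": {"type": "number", "exclusiveMinimum": 0},
    "exposure_ms": {"type": "number", "exclusiveMinimum": 0},
    "detector_distance_mm": {"type": "number", "exclusiveMinimum": 0},
    "flux": {"type": "number", "minimum": 0}
  },
  "required": ["wavelength_A", "step_um"]
}
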