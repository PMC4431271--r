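{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "adlsim context-knowledge file",
  "description": "Objects of the simulated environment, the sensors attached to them, and per-sensor-type missing-noise probabilities.",
  "type": "object",
  "required": ["objects", "sensors", "error_models"],
  "properties": {
    "objects": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "location", "attached_sensor"],
        "properties": {
          "name": {"type": "string"},
          "location": {"type": "string", "description": "free-form identifier, carried through but not interpreted"},
          "attached_sensor": {"type": "string", "description": "must name an entry of 'sensors'"}
        }
      }
    },
    "sensors": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "type"],
        "properties": {
          "name": {"type": "string"},
          "type": {"type": "string", "description": "must have an entry in 'error_models'"}
        }
      }
    },
    "error_models": {
      "type": "object",
      "description": "sensor type -> probability that a real interaction produces no activation",
      "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}
    }
  }
}
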