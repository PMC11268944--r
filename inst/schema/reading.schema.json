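{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "$id": "https://example.org/sdmkit/reading.schema.json",
  "title": "Canonical structured-test reading",
  "type": "object",
  "required": ["metadata", "levels"],
  "properties": {
    "metadata": {
      "type": "object",
      "required": ["evaluation_code", "subject_id", "session_id"],
      "properties": {
        "evaluation_code": {"type": "string", "pattern": "^[a-z0-9_]+$"},
        "subject_id": {"type": "string"},
        "session_id": {"type": "string"},
        "schema_version": {"type": "string"},
        "device": {"type": "object"}
      },
      "additionalProperties": true
    },
    "levels": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "start", "end", "datasets"],
        "properties": {
          "id": {"type": "string", "pattern": "^[a-z0-9_]+$"},
          "modalities": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["dimension", "value"],
              "properties": {
                "dimension": {"type": "string"},
                "value": {"type": "string", "pattern": "^[a-z0-9_]+$"}
              }
            }
          },
          "start": {"type": "number"},
          "end": {"type": "number"},
          "context": {"type": "object"},
          "datasets": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["id", "source", "columns", "values"],
              "properties": {
                "id": {"type": "string", "pattern": "^[a-z0-9_]+$"},
                "source": {
                  "type": "object",
                  "properties": {
                    "device_model": {"type": "string"},
                    "sensor": {"type": "string"},
                    "sampling_frequency": {"type": ["number", "null"]},
                    "placement": {"enum": ["handheld", "belt", "none"]}
                  }
                },
                "columns": {
                  "type": "array",
                  "minItems": 1,
                  "items": {
                    "type": "object",
                    "required": ["id", "data_type"],
                    "properties": {
                      "id": {"type": "string"},
                      "name": {"type": "string"},
                      "unit": {"type": "string"},
                      "data_type": {
                        "enum": ["float", "int", "bool", "string", "timestamp"]
                      },
                      "valid_range": {
                        "type": "array",
                        "items": {"type": "number"},
                        "minItems": 2, "maxItems": 2
                      }
                    }
                  }
                },
                "values": {
                  "type": "array",
                  "items": {"type": "array"},
                  "description": "column-major; one array per column, equal lengths"
                }
              }
            }
          },
          "epochs": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["definition", "start", "end"],
              "properties": {
                "definition": {"type": "object"},
                "start": {"type": "number"},
                "end": {"type": "number"},
                "payload": {"type": "object"}
              }
            }
          },
          "measures": {"type": "array", "items": {"type": "object"}},
          "flags": {"type": "array", "items": {"type": "object"}}
        }
      }
    },
    "measures": {"type": "array", "items": {"type": "object"}},
    "flags": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "targets"],
        "properties": {
          "id": {
            "type": "string",
            "pattern": "^[a-z0-9_]+-(technical|behavioral)-(deviation|invalidation)-[a-z0-9_]+$"
          },
          "reason": {"type": "string"},
          "targets": {"type": "array", "items": {"type": "string"}},
          "stopped_processing": {"type": "boolean"}
        }
      }
    }
  }
}
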