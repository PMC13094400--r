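{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Minimal HML message (JSON serialisation)",
  "type": "object",
  "required": ["hml"],
  "properties": {
    "hml": {
      "type": "object",
      "required": ["message_id", "samples"],
      "properties": {
        "version": {"type": "string"},
        "created": {"type": "string"},
        "message_id": {"type": "string", "minLength": 1},
        "reporting_center": {"type": "string"},
        "extras": {"type": "array", "items": {"type": "string"}},
        "samples": {
          "type": "array",
          "minItems": 1,
          "items": {
            "type": "object",
            "required": ["sample_id"],
            "properties": {
              "sample_id": {"type": "string", "minLength": 1},
              "properties": {
                "type": "object",
                "additionalProperties": {"type": "string"}
              },
              "extras": {"type": "array", "items": {"type": "string"}},
              "typings": {
                "type": "array",
                "items": {
                  "type": "object",
                  "required": ["allele_assignment"],
                  "properties": {
                    "gene_family": {"type": "string"},
                    "allele_assignment": {
                      "type": "object",
                      "properties": {
                        "allele_db": {"type": "string"},
                        "allele_version": {"type": "string"},
                        "date": {"type": "string"},
                        "glstring": {"type": "string"}
                      }
                    },
                    "typing_method": {
                      "type": "object",
                      "required": ["description"],
                      "properties": {
                        "description": {"type": "string", "minLength": 1},
                        "platform": {"type": "string"},
                        "exons_targeted": {
                          "type": "array",
                          "items": {"type": "integer"}
                        },
                        "software": {"type": "string"},
                        "software_version": {"type": "string"}
                      }
                    },
                    "consensus_sequence": {"type": "string"},
                    "extras": {"type": "array", "items": {"type": "string"}}
                  }
                }
              }
            }
          }
        }
      }
    }
  }
}
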