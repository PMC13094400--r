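{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "Compliance validation report",
  "type": "object",
  "required": ["message_ref", "tier_requested", "rules", "verdicts",
               "toolkit_version", "catalog_version", "timestamp"],
  "properties": {
    "message_ref": {"type": "string"},
    "tier_requested": {"enum": ["Minimal", "General", "Optional"]},
    "reference_release": {"type": ["string", "null"]},
    "timestamp": {"type": "string"},
    "toolkit_version": {"type": "string"},
    "catalog_version": {"type": "string"},
    "verdicts": {
      "type": "object",
      "additionalProperties": {"enum": ["pass", "fail"]}
    },
    "rules": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["rule_id", "tier", "severity", "outcome", "evidence",
                     "description", "corrective_action"],
        "properties": {
          "rule_id": {"type": "string"},
          "tier": {"enum": ["Minimal", "General", "Optional"]},
          "severity": {"enum": ["error", "warning", "info"]},
          "outcome": {"enum": ["pass", "fail", "not_evaluated"]},
          "evidence": {"type": "string"},
          "description": {"type": "string"},
          "corrective_action": {"type": "string"}
        }
      }
    }
  }
}
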