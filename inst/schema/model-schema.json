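{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "reconarm model document",
  "description": "Normative schema for serialized articulated upper-limb models (format 'reconarm-model', version 1.0). Units are fixed by the units block: lengths m, masses kg, angles rad, forces N, inertia kg.m^2. Bodies are listed root-first; the root has neither parent nor joint. Joints are fixed offsets followed by an ordered intrinsic rotation sequence. Round-trip read/write must be lossless.",
  "type": "object",
  "required": ["format", "version", "units", "variant", "bodies", "muscles", "wraps", "hand_point"],
  "properties": {
    "format": { "const": "reconarm-model" },
    "version": { "type": "string" },
    "units": { "type": "object" },
    "variant": { "enum": ["lumpectomy", "implant", "flap"] },
    "bodies": {
      "type": "array", "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "mass", "com", "inertia"],
        "properties": {
          "name": { "type": "string" },
          "mass": { "type": "number", "minimum": 0 },
          "com": { "type": "array", "items": { "type": "number" }, "minItems": 3, "maxItems": 3 },
          "inertia": { "type": "array", "minItems": 3, "maxItems": 3,
            "items": { "type": "array", "items": { "type": "number" }, "minItems": 3, "maxItems": 3 } },
          "parent": { "type": "string" },
          "joint": {
            "type": "object",
            "required": ["name", "axes", "coords", "range_min", "range_max", "offset_p", "offset_R"],
            "properties": {
              "name": { "type": "string" },
              "axes": { "type": "array", "items": { "type": "array", "items": { "type": "number" } } },
              "coords": { "type": "array", "items": { "type": "string" } },
              "range_min": { "type": "array", "items": { "type": "number" } },
              "range_max": { "type": "array", "items": { "type": "number" } },
              "offset_p": { "type": "array", "items": { "type": "number" } },
              "offset_R": { "type": "array", "items": { "type": "array", "items": { "type": "number" } } }
            }
          }
        }
      }
    },
    "muscles": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "compartment", "fmax", "lopt", "points"],
        "properties": {
          "name": { "type": "string" },
          "compartment": { "type": "string" },
          "fmax": { "type": "number", "exclusiveMinimum": 0 },
          "lopt": { "type": "number", "exclusiveMinimum": 0 },
          "points": {
            "type": "array", "minItems": 2,
            "items": {
              "type": "object",
              "required": ["body", "location"],
              "properties": {
                "body": { "type": "string" },
                "location": { "type": "array", "items": { "type": "number" }, "minItems": 3, "maxItems": 3 }
              }
            }
          },
          "wrap": { "type": "string" },
          "wrap_segment": { "type": "integer", "minimum": 1 }
        }
      }
    },
    "wraps": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "body", "center", "axis", "radius", "half_length", "wrap_side", "applies_to"],
        "properties": {
          "id": { "type": "string" },
          "body": { "type": "string" },
          "center": { "type": "array", "items": { "type": "number" } },
          "axis": { "type": "array", "items": { "type": "number" } },
          "radius": { "type": "number", "exclusiveMinimum": 0 },
          "half_length": { "type": "number", "exclusiveMinimum": 0 },
          "wrap_side": { "type": "array", "items": { "type": "number" } },
          "applies_to": { "type": "array", "items": { "type": "string" } }
        }
      }
    },
    "hand_point": {
      "type": "object",
      "required": ["body", "location"],
      "properties": {
        "body": { "type": "string" },
        "location": { "type": "array", "items": { "type": "number" } }
      }
    }
  }
}
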