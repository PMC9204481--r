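{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "plaqrupt annotated OCT pullback, schema_version 1",
  "type": "object",
  "required": ["schema_version", "frame_spacing_mm", "group", "frames"],
  "properties": {
    "schema_version": {"const": 1},
    "id": {"type": "string"},
    "frame_spacing_mm": {"enum": [0.4, 0.375]},
    "group": {"enum": ["PR-NV", "PR-NA"]},
    "vessel": {"enum": ["LAD", "LCx", "RCA"]},
    "patient_meta": {"type": "object"},
    "frames": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["frame_index", "z_mm"],
        "properties": {
          "frame_index": {"type": "integer", "minimum": 0},
          "z_mm": {"type": "number"},
          "lumen_radius": {
            "type": "array", "minItems": 36,
            "items": {"type": "number", "exclusiveMinimum": 0},
            "description": "angular radius samples (mm), uniform over 360 deg, 0 deg at 3 o'clock, counter-clockwise; required when lumen_area_mm2 is absent"
          },
          "lumen_area_mm2": {"type": "number", "exclusiveMinimum": 0},
          "eem_area_mm2": {"type": "number", "exclusiveMinimum": 0,
            "description": "must be >= the lumen area; omitted when the EEM is not visible"},
          "stent_area_mm2": {"type": "number", "exclusiveMinimum": 0},
          "neointima_thickness_mm": {"type": "number", "minimum": 0},
          "arcs": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["start_deg", "end_deg", "kind"],
              "properties": {
                "start_deg": {"type": "number", "minimum": 0, "exclusiveMaximum": 360},
                "end_deg": {"type": "number", "minimum": 0, "exclusiveMaximum": 360},
                "kind": {"enum": ["lipid", "calcific", "macrophage_spotted",
                                  "macrophage_lined", "rupture", "thrombus"]}
              }
            }
          },
          "cap_thickness_um": {
            "type": "array", "items": {"type": "number", "exclusiveMinimum": 0},
            "description": "fibrous-cap thickness samples over the frame's lipid arcs"
          },
          "rupture_present": {"type": "boolean"},
          "approximated_lumen_radius": {
            "type": "array", "items": {"type": "number", "exclusiveMinimum": 0},
            "description": "reconstructed pre-rupture lumen border (mm); only on rupture frames"
          },
          "rupture_depth_mm": {"type": "number", "minimum": 0},
          "thrombus_quadrants": {
            "type": "array", "minItems": 4, "maxItems": 4,
            "items": {"type": "boolean"},
            "description": "quadrant 1 spans 0-90 deg, counter-clockwise"
          },
          "microchannel_diameter_um": {"type": "number", "exclusiveMinimum": 0},
          "cholesterol_crystal": {"type": "boolean"},
          "meta": {"type": "object",
            "description": "free-form map; unknown frame fields are preserved here on read"}
        }
      }
    }
  }
}
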