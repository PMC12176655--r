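{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "liveqibc lineage forest document",
  "type": "object",
  "required": ["schema", "frames", "meta", "edges", "divisions", "points"],
  "properties": {
    "schema": {"const": "liveqibc-lineage-v1"},
    "frames": {"type": "array", "items": {"type": "integer"}},
    "meta": {
      "type": "object",
      "required": ["track", "start_frame", "end_frame", "birth_type",
                   "end_type", "parent", "tree", "depth", "generation"],
      "properties": {
        "track": {"type": "array", "items": {"type": "integer"}},
        "start_frame": {"type": "array", "items": {"type": "integer"}},
        "end_frame": {"type": "array", "items": {"type": "integer"}},
        "birth_type": {"type": "array",
                       "items": {"enum": ["movie_start", "appearance"]}},
        "end_type": {"type": "array",
                     "items": {"enum": ["movie_end", "loss", "division"]}},
        "parent": {"type": "array",
                   "items": {"type": ["integer", "null"]}},
        "tree": {"type": "array", "items": {"type": "integer"}},
        "depth": {"type": "array", "items": {"type": "integer"}},
        "generation": {"type": "array", "items": {"type": "string"}}
      }
    },
    "edges": {
      "type": "object",
      "required": ["parent", "daughter"],
      "properties": {
        "parent": {"type": "array", "items": {"type": "integer"}},
        "daughter": {"type": "array", "items": {"type": "integer"}}
      }
    },
    "divisions": {
      "type": "object",
      "required": ["parent", "daughter1", "daughter2", "parent_end_frame",
                   "daughter_start_frame"]
    },
    "points": {
      "type": "object",
      "required": ["frame", "label", "track", "x", "y"]
    },
    "endpoints": {
      "type": ["object", "null"],
      "description": "per final-frame leaf: endpoint marker vector, DNA class, lost_at_fixation flag"
    },
    "endpoint_summary": {"type": ["object", "null"]}
  }
}
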