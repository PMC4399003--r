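{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "haphseg pipeline run report",
  "type": "object",
  "required": ["version", "seed", "stages"],
  "properties": {
    "version": {"type": "string"},
    "seed": {"type": "integer"},
    "stages": {"type": "array", "items": {"type": "string"}},
    "simulate": {"type": "object"},
    "diversity": {"type": "object"},
    "filter": {"type": "object"},
    "assoc": {"type": "object"},
    "enrich": {"type": "object"}
  }
}
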