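{
  "title": "afpoverty pipeline report",
  "required": {
    "package_version": "string",
    "seed": "integer",
    "k": "number",
    "inclusive": "boolean",
    "level": "number",
    "n_households": "integer",
    "n_eas": "integer",
    "headcount": "number",
    "headcount_ci": "array",
    "intensity": "number",
    "intensity_ci": "array",
    "adjusted_headcount": "number",
    "adjusted_headcount_ci": "array",
    "censored_headcounts": "object",
    "contributions": "object",
    "dimension_contributions": "object",
    "groups": "object",
    "robustness": "object",
    "wealth": "object"
  }
}
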