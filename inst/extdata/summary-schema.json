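{
  "title": "srvpulse pipeline summary",
  "required": [
    "seed",
    "n_channels",
    "diameter_amplitude_pct",
    "area_amplitude_pct",
    "sensitivity_ratio",
    "flow_oscillation_pct",
    "delay_s",
    "delay_detectable",
    "pwv_mm_s",
    "max_resolvable_pwv_mm_s",
    "conservation_r",
    "intensity_modality_r"
  ],
  "properties": {
    "preset": "string",
    "seed": "integer",
    "config_fingerprint": "string",
    "n_channels": "integer",
    "diameter_amplitude_pct": "number",
    "area_amplitude_pct": "number",
    "sensitivity_ratio": "number",
    "flow_oscillation_pct": "number",
    "delay_s": "number",
    "delay_detectable": "boolean",
    "pwv_mm_s": "number",
    "max_resolvable_pwv_mm_s": "number",
    "conservation_r": "number",
    "intensity_modality_r": "number"
  }
}
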