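[
  {
    "name": "within_1h",
    "rrr_point": 0.32,
    "rrr_low": 0.18,
    "rrr_high": 0.43,
    "subgroup_source": "all",
    "subgroup_fallback": 1.0,
    "window_label": "<1 h of injury, all severe traumas"
  },
  {
    "name": "1_to_3h",
    "rrr_point": 0.21,
    "rrr_low": 0.03,
    "rrr_high": 0.36,
    "subgroup_source": "all",
    "subgroup_fallback": 1.0,
    "window_label": "1-3 h after injury (defer to hospital)"
  },
  {
    "name": "hypotensive_only_1h",
    "rrr_point": 0.32,
    "rrr_low": 0.18,
    "rrr_high": 0.43,
    "subgroup_source": "p_hypotensive",
    "subgroup_fallback": 0.181,
    "window_label": "<1 h, restricted to prehospital hypotension"
  },
  {
    "name": "hypo_or_tachy_1h",
    "rrr_point": 0.32,
    "rrr_low": 0.18,
    "rrr_high": 0.43,
    "subgroup_source": "p_tachy_or_hypo",
    "subgroup_fallback": 0.402,
    "window_label": "<1 h, restricted to prehospital hypotension or tachycardia"
  }
]
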