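{
  "schema": "mirrorscreen/triage-config/v1",
  "ptsd_cutoffs": [9, 14],
  "functioning_cutoffs": [4, 6],
  "resilience_cutoff": 9,
  "decision_table": [
    {
      "ptsd_level": "low",
      "functioning_level": "low",
      "phase": "under_1_week",
      "color": "red"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "low",
      "phase": "under_1_week",
      "color": "red"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "low",
      "phase": "under_1_week",
      "color": "red"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "moderate",
      "phase": "under_1_week",
      "color": "green"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "moderate",
      "phase": "under_1_week",
      "color": "orange"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "moderate",
      "phase": "under_1_week",
      "color": "orange"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "high",
      "phase": "under_1_week",
      "color": "green"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "high",
      "phase": "under_1_week",
      "color": "green"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "high",
      "phase": "under_1_week",
      "color": "orange"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "low",
      "phase": "one_to_4_weeks",
      "color": "red"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "low",
      "phase": "one_to_4_weeks",
      "color": "red"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "low",
      "phase": "one_to_4_weeks",
      "color": "red"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "moderate",
      "phase": "one_to_4_weeks",
      "color": "green"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "moderate",
      "phase": "one_to_4_weeks",
      "color": "orange"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "moderate",
      "phase": "one_to_4_weeks",
      "color": "orange"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "high",
      "phase": "one_to_4_weeks",
      "color": "green"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "high",
      "phase": "one_to_4_weeks",
      "color": "green"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "high",
      "phase": "one_to_4_weeks",
      "color": "orange"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "low",
      "phase": "over_4_weeks",
      "color": "red"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "low",
      "phase": "over_4_weeks",
      "color": "red"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "low",
      "phase": "over_4_weeks",
      "color": "red"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "moderate",
      "phase": "over_4_weeks",
      "color": "green"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "moderate",
      "phase": "over_4_weeks",
      "color": "red"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "moderate",
      "phase": "over_4_weeks",
      "color": "red"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "high",
      "phase": "over_4_weeks",
      "color": "green"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "high",
      "phase": "over_4_weeks",
      "color": "green"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "high",
      "phase": "over_4_weeks",
      "color": "orange"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "low",
      "phase": "recurring",
      "color": "red"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "low",
      "phase": "recurring",
      "color": "red"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "low",
      "phase": "recurring",
      "color": "red"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "moderate",
      "phase": "recurring",
      "color": "green"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "moderate",
      "phase": "recurring",
      "color": "red"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "moderate",
      "phase": "recurring",
      "color": "red"
    },
    {
      "ptsd_level": "low",
      "functioning_level": "high",
      "phase": "recurring",
      "color": "green"
    },
    {
      "ptsd_level": "moderate",
      "functioning_level": "high",
      "phase": "recurring",
      "color": "green"
    },
    {
      "ptsd_level": "high",
      "functioning_level": "high",
      "phase": "recurring",
      "color": "orange"
    }
  ]
}
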