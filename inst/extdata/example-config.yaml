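# Example simulation configuration. Omitted fields fall back to the
# package defaults (200 patients, 6 weeks, published baseline
# probabilities, boost 0.15 on every default correlation rule).
n_patients: 50
n_weeks: 6
seed: 42
susceptibility: {mean: 1.0, sd: 0.20, lower: 0.5, upper: 1.8, method: truncate}
correlation_rules:
  - {trigger: fatigue,  target: insomnia,       boost: 0.15}
  - {trigger: nausea,   target: vomiting,       boost: 0.15}
  - {trigger: diarrhea, target: abdominal_pain, boost: 0.15}
  - {trigger: fatigue,  target: cephalea,       boost: 0.15}
  - {trigger: nausea,   target: cephalea,       boost: 0.15}
  - {trigger: vomiting, target: cephalea,       boost: 0.15}
  - {trigger: fatigue,  target: pyrexia,        boost: 0.15}
  - {trigger: nausea,   target: weight_loss,    boost: 0.15}
  - {trigger: vomiting, target: weight_loss,    boost: 0.15}
  - {trigger: diarrhea, target: weight_loss,    boost: 0.15}
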