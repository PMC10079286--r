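# Example evaluation configuration for run_evaluation() /
# inst/scripts/screendisrupt.R. Durations are disruption lengths in
# months; each runs against a seed-paired status quo counterfactual.
programmes: [breast, bowel, cervix]
durations:
  breast: [3, 6, 12]
  bowel: [3, 6, 12]
  cervix: [6, 9, 12]
seed: 1
scale: 0.01    # 1:100 of the national eligible populations
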