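# Demo pipeline configuration: a small synthetic cohort with an exaggerated
# carrier frequency so every joint category is populated at this size.
# Study-scale runs use nIndividuals: 3220 and carrierFreq: 0.006.
seed: 20260923
simulate:
  nIndividuals: 900
  nPrsVariants: 60
  carrierFreq: 0.08
  caseFraction: 0.5
  n_plpd: 12
  n_benign: 20
outcomes:
  - overall
  - aggressive
  - nonaggressive
absrisk:
  n_iter: 100
  age_start: 40
  age_end: 85
  prevalence: 0.167
  w_aggressive: 0.37
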