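# SYNTHETIC demonstration signature. The gene list names real proliferation
# markers but the coefficients are illustrative only — they were not fitted
# on any cohort and carry no published provenance. Bundled so the
# weighted-sum original-method archetype is exercised end to end.
id: proliferation_demo
keywords: [proliferation, demo, synthetic, weighted]
doi: ""
description: >
  Synthetic weighted-sum demonstration signature over canonical
  proliferation markers. Coefficients are illustrative, not fitted;
  do not use for inference.
method: weighted_sum
up:
  - MKI67
  - TOP2A
  - BIRC5
  - CCNB1
  - AURKA
coefficients:
  MKI67: 0.40
  TOP2A: 0.30
  BIRC5: 0.20
  CCNB1: 0.15
  AURKA: -0.05
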