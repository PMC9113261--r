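id: cytolytic_rooney
keywords: [immune, cytolytic, cyt]
doi: 10.1016/j.cell.2014.12.033
description: >
  Immune cytolytic activity. The original score is the geometric mean of
  GZMA and PRF1 transcript levels; on log-scale input the arithmetic mean
  is the equivalent statistic, which is what the original method computes
  here.
method: mean
up:
  - GZMA
  - PRF1
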