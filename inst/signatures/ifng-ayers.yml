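id: ifng_ayers
keywords: [immune, ifng, interferon, pembrolizumab]
doi: 10.1172/JCI91190
description: >
  6-gene interferon-gamma signature associated with clinical response to
  PD-1 blockade. Original score: arithmetic mean of normalized (log10)
  expression of the signature genes.
method: mean
up:
  - IFNG
  - STAT1
  - IDO1
  - CXCL10
  - CXCL9
  - HLA-DRA
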