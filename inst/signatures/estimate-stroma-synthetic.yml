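# SYNTHETIC stand-in gene list — see note in estimate-immune-synthetic.yml.
id: estimate_stroma
keywords: [estimate, stroma, stromal, purity, microenvironment]
doi: 10.1038/ncomms3612
description: >
  Stromal infiltration gene set for ESTIMATE-style tumor purity scoring
  (ssGSEA, alpha = 0.25, raw). Bundled list is a synthetic demonstration
  stand-in for the published 141-gene set.
method: dedicated_estimate
up:
  - COL1A1
  - COL1A2
  - COL3A1
  - COL5A1
  - COL5A2
  - COL6A3
  - COL8A1
  - FAP
  - ACTA2
  - PDGFRA
  - PDGFRB
  - FN1
  - THBS2
  - DCN
  - LUM
  - FBN1
  - POSTN
  - SPARC
  - VCAN
  - MMP2
  - TAGLN
  - MYL9
  - ZEB1
  - TWIST1
  - SNAI2
  - CDH11
  - FGF7
  - VIM
  - TNC
  - SULF1
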