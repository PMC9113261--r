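# SYNTHETIC stand-in gene list. The published immune signature for this
# method (see doi) has 141 genes; the list below is a demonstration set of
# canonical leukocyte / lymphocyte markers with the same biological intent,
# NOT the published list. Replace `up` with the published 141 genes for
# faithful scores; the purity coefficients in estimate-purity.yml ARE the
# published values.
id: estimate_immune
keywords: [estimate, immune, purity, microenvironment]
doi: 10.1038/ncomms3612
description: >
  Immune cell infiltration gene set for ESTIMATE-style tumor purity
  scoring (ssGSEA, alpha = 0.25, raw). Bundled list is a synthetic
  demonstration stand-in for the published 141-gene set.
method: dedicated_estimate
up:
  - CD2
  - CD3D
  - CD3E
  - CD3G
  - CD8A
  - CD8B
  - CD27
  - CD28
  - CD48
  - CD52
  - CD53
  - GZMA
  - GZMB
  - GZMK
  - PRF1
  - CCL5
  - CXCL9
  - CXCL10
  - CXCL11
  - IL7R
  - IL2RG
  - LCK
  - ZAP70
  - PTPRC
  - SASH3
  - ITGAL
  - KLRB1
  - KLRD1
  - NKG7
  - TIGIT
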