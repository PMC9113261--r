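# SYNTHETIC stand-in gene list. The published sarcoma prognostic signature
# for this method (see doi) has 67 genes related to mitosis and chromosome
# integrity; the list below is a demonstration set of canonical
# mitosis/chromosome-segregation genes with the same biological intent, NOT
# the published list. Replace `up` with the published 67 genes for faithful
# classification.
id: cinsarc
keywords: [cinsarc, sarcoma, metastasis, risk, mitosis]
doi: 10.1038/nm.2174
description: >
  Mitosis / chromosome-integrity gene set for CINSARC-style nearest-centroid
  risk classification (C1 low risk / C2 high risk, leave-one-out centroids).
  Bundled list is a synthetic demonstration stand-in for the published
  67-gene set.
method: dedicated_cinsarc
up:
  - AURKA
  - AURKB
  - BIRC5
  - BUB1
  - BUB1B
  - CCNB1
  - CCNB2
  - CDK1
  - CDC20
  - CENPA
  - CENPE
  - CENPF
  - CHEK1
  - ESPL1
  - FOXM1
  - KIF11
  - KIF14
  - KIF15
  - KIF23
  - KIF2C
  - KIF4A
  - MAD2L1
  - MCM2
  - MELK
  - NCAPH
  - NDC80
  - NUF2
  - OIP5
  - PBK
  - PLK1
  - PRC1
  - PTTG1
  - RRM2
  - SPAG5
  - TOP2A
  - TPX2
  - TRIP13
  - TTK
  - UBE2C
  - ZWINT
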