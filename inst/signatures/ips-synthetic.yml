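# SYNTHETIC stand-in marker table. The published immunophenogram (see doi)
# defines ~26 weighted markers in four categories (MHC molecules, effector
# cells, suppressor cells, checkpoints), several of which are multi-gene
# cell-type metagenes. The table below reproduces the STRUCTURE (categories,
# weight signs, aggregation) with demonstration gene lists, NOT the published
# metagene memberships. Edit the markers to the published table for faithful
# scores.
id: immunophenoscore
keywords: [ips, immunophenoscore, immune, checkpoint, immunogenicity]
doi: 10.1016/j.celrep.2016.12.019
description: >
  Immunophenoscore-style weighted aggregation of immune marker z-scores
  into four category scores (MHC, EC, SC, CP), an aggregate score and a
  0-10 integer score. Bundled marker table is a synthetic demonstration
  stand-in for the published one.
method: dedicated_ips
markers:
  - {name: B2M,      category: MHC, weight: 1,  genes: [B2M]}
  - {name: TAP1,     category: MHC, weight: 1,  genes: [TAP1]}
  - {name: TAP2,     category: MHC, weight: 1,  genes: [TAP2]}
  - {name: HLA-A,    category: MHC, weight: 1,  genes: [HLA-A]}
  - {name: HLA-B,    category: MHC, weight: 1,  genes: [HLA-B]}
  - {name: HLA-C,    category: MHC, weight: 1,  genes: [HLA-C]}
  - {name: HLA-DPA1, category: MHC, weight: 1,  genes: [HLA-DPA1]}
  - {name: HLA-DPB1, category: MHC, weight: 1,  genes: [HLA-DPB1]}
  - {name: HLA-E,    category: MHC, weight: 1,  genes: [HLA-E]}
  - {name: HLA-F,    category: MHC, weight: 1,  genes: [HLA-F]}
  - {name: Act_CD8,  category: EC,  weight: 1,  genes: [CD8A, GZMB, PRF1, IFNG]}
  - {name: Act_CD4,  category: EC,  weight: 1,  genes: [CD4, IL2, CD40LG]}
  - {name: Tem_CD8,  category: EC,  weight: 1,  genes: [EOMES, GZMK, KLRG1]}
  - {name: Tem_CD4,  category: EC,  weight: 1,  genes: [IL7R, CD44, SELL]}
  - {name: Treg,     category: SC,  weight: -1, genes: [FOXP3, IL2RA, IKZF2]}
  - {name: MDSC,     category: SC,  weight: -1, genes: [CD33, ITGAM, ARG1]}
  - {name: PD-1,     category: CP,  weight: -1, genes: [PDCD1]}
  - {name: CTLA-4,   category: CP,  weight: -1, genes: [CTLA4]}
  - {name: LAG-3,    category: CP,  weight: -1, genes: [LAG3]}
  - {name: TIM-3,    category: CP,  weight: -1, genes: [HAVCR2]}
  - {name: PD-L1,    category: CP,  weight: -1, genes: [CD274]}
  - {name: PD-L2,    category: CP,  weight: -1, genes: [PDCD1LG2]}
  - {name: TIGIT,    category: CP,  weight: -1, genes: [TIGIT]}
  - {name: IDO1,     category: CP,  weight: -1, genes: [IDO1]}
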