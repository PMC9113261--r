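# Tumor purity mapping: purity = cos(a + b * estimate_score), valid on the
# monotone-decreasing branch of the cosine (argument in [0, pi]).
# These coefficient values are the ones published for the ESTIMATE method
# (Affymetrix-calibrated); source below.
doi: 10.1038/ncomms3612
a: 0.6049872018
b: 0.0001467884
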