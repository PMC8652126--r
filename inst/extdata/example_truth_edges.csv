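gene_a,gene_b,partial_correlation
g1,g2,0.520265981714472
g2,g4,-0.520265981714472
g2,g7,-0.520265981714472
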