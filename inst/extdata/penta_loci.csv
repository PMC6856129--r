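Locus,Chromosome,Map_cM
PentaD,21,59.3759
PentaE,15,124.05054
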