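#format=pgxkb-1 build=GRCh38
gene	allele
HLA-B	HLA-B*57:01
HLA-B	HLA-B*15:02
HLA-A	HLA-A*31:01
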