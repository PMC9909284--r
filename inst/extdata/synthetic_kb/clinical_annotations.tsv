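#format=pgxkb-1 build=GRCh38
annotation_id	drug	gene	genotype_key	evidence_level	category	direction
ANN0001	drug01	CYP2B6	*1/*2	1B	dosage	increased
ANN0002	drug01	CYP2B6	*2/*2	1B	efficacy	increased
ANN0003	drug02	CYP2C19	*1/*2	2A	toxicity	increased
ANN0004	drug02	CYP2C19	*2/*2	1B	dosage	increased
ANN0005	drug03	CYP2C8	*1/*2	2B	metabolism	decreased
ANN0006	drug03	CYP2C8	*2/*2	2B	toxicity	normal
ANN0007	drug04	CYP2C9	*1/*2	2B	dosage	decreased
ANN0008	drug04	CYP2C9	*2/*2	1A	metabolism	normal
ANN0009	drug05	CYP2D6	*1/*2	2A	toxicity	normal
ANN0010	drug05	CYP2D6	*2/*2	1A	metabolism	increased
ANN0011	drug06	CYP3A4	*1/*2	2A	efficacy	decreased
ANN0012	drug06	CYP3A4	*2/*2	2A	metabolism	increased
ANN0013	drug07	CYP3A5	*1/*2	2B	dosage	decreased
ANN0014	drug07	CYP3A5	*2/*2	1A	dosage	decreased
ANN0015	drug08	CYP4F2	*1/*2	2A	toxicity	increased
ANN0016	drug08	CYP4F2	*2/*2	2B	dosage	increased
ANN0017	drug09	DPYD	*1/*2	1B	toxicity	decreased
ANN0018	drug09	DPYD	*2/*2	2A	dosage	normal
ANN0019	drug10	NUDT15	*1/*2	1B	toxicity	normal
ANN0020	drug10	NUDT15	*2/*2	1B	toxicity	normal
ANN0021	drug11	SLCO1B1	*1/*2	1B	metabolism	normal
ANN0022	drug11	SLCO1B1	*2/*2	2B	dosage	increased
ANN0023	drug12	TPMT	*1/*2	1B	efficacy	normal
ANN0024	drug12	TPMT	*2/*2	2A	efficacy	increased
ANN0025	drug13	UGT1A1	*1/*2	2B	toxicity	decreased
ANN0026	drug13	UGT1A1	*2/*2	1B	toxicity	increased
ANN0027	drugSV	VKORC1	C/T	1A	metabolism	decreased
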