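#format=pgxkb-1 build=GRCh38
source	drug	gene	genotype_key	category	population_dependent	multi_gene	text
CPIC	drug01	CYP2B6	*4/*4	avoid	0	0	Adjust therapy for CYP2B6 *4/*4 carriers.
DPWG	drug01	CYP2B6	*1/*2	routine	0	0	No change for CYP2B6 *1/*2.
CPIC	drug02	CYP2C19	*4/*4	caution	0	0	Adjust therapy for CYP2C19 *4/*4 carriers.
DPWG	drug02	CYP2C19	*1/*2	routine	1	0	No change for CYP2C19 *1/*2.
CPIC	drug03	CYP2C8	*3/*3	caution	0	0	Adjust therapy for CYP2C8 *3/*3 carriers.
DPWG	drug03	CYP2C8	*1/*2	routine	0	0	No change for CYP2C8 *1/*2.
CPIC	drug04	CYP2C9	*7/*7	caution	0	0	Adjust therapy for CYP2C9 *7/*7 carriers.
DPWG	drug04	CYP2C9	*1/*2	routine	0	0	No change for CYP2C9 *1/*2.
CPIC	drug05	CYP2D6	*5/*5	caution	0	0	Adjust therapy for CYP2D6 *5/*5 carriers.
DPWG	drug05	CYP2D6	*1/*2	routine	0	0	No change for CYP2D6 *1/*2.
CPIC	drug06	CYP3A4	*5/*5	caution	0	0	Adjust therapy for CYP3A4 *5/*5 carriers.
DPWG	drug06	CYP3A4	*1/*2	routine	0	0	No change for CYP3A4 *1/*2.
CPIC	drug07	CYP3A5	*7/*7	caution	0	0	Adjust therapy for CYP3A5 *7/*7 carriers.
DPWG	drug07	CYP3A5	*1/*2	routine	0	0	No change for CYP3A5 *1/*2.
CPIC	drug08	CYP4F2	*6/*6	caution	0	0	Adjust therapy for CYP4F2 *6/*6 carriers.
DPWG	drug08	CYP4F2	*1/*2	routine	0	0	No change for CYP4F2 *1/*2.
CPIC	drug09	DPYD	*4/*4	caution	0	0	Adjust therapy for DPYD *4/*4 carriers.
DPWG	drug09	DPYD	*1/*2	routine	0	0	No change for DPYD *1/*2.
CPIC	drug10	NUDT15	*6/*6	caution	0	0	Adjust therapy for NUDT15 *6/*6 carriers.
DPWG	drug10	NUDT15	*1/*2	routine	0	0	No change for NUDT15 *1/*2.
CPIC	drug11	SLCO1B1	*4/*4	caution	0	0	Adjust therapy for SLCO1B1 *4/*4 carriers.
DPWG	drug11	SLCO1B1	*1/*2	routine	0	0	No change for SLCO1B1 *1/*2.
CPIC	drug12	TPMT	*6/*6	caution	0	0	Adjust therapy for TPMT *6/*6 carriers.
DPWG	drug12	TPMT	*1/*2	routine	0	0	No change for TPMT *1/*2.
CPIC	drug13	UGT1A1	*6/*6	caution	0	0	Adjust therapy for UGT1A1 *6/*6 carriers.
DPWG	drug13	UGT1A1	*1/*2	routine	0	0	No change for UGT1A1 *1/*2.
CPIC	drugHLA	HLA-B	HLA-B*57:01	avoid	0	0	Do not use in carriers.
RNPGx	drugSV	VKORC1	T/T	caution	0	0	Reduce dose for homozygous carriers.
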