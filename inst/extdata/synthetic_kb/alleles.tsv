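#format=pgxkb-1 build=GRCh38
gene	haplotype	chromosome	position	ref	alt	is_reference
CYP2B6	*1					1
CYP2B6	*2	chr19	1002621	A	C	0
CYP2B6	*3	chr19	1008397	C	G	0
CYP2B6	*4	chr19	1002621	A	C	0
CYP2B6	*4	chr19	1008397	C	G	0
CYP2C19	*1					1
CYP2C19	*2	chr10	2024225	G	C	0
CYP2C19	*2	chr10	2031545	G	A	0
CYP2C19	*2	chr10	2038023	C	T	0
CYP2C19	*3	chr10	2011257	G	A	0
CYP2C19	*3	chr10	2024225	G	C	0
CYP2C19	*3	chr10	2031545	G	A	0
CYP2C19	*4	chr10	2023396	C	G	0
CYP2C19	*4	chr10	2031545	G	A	0
CYP2C8	*1					1
CYP2C8	*2	chr10	3032006	G	T	0
CYP2C8	*3	chr10	3027606	G	T	0
CYP2C9	*1					1
CYP2C9	*2	chr10	4029730	G	A	0
CYP2C9	*2	chr10	4030845	T	G	0
CYP2C9	*3	chr10	4024190	A	G	0
CYP2C9	*3	chr10	4029730	G	A	0
CYP2C9	*4	chr10	4024190	A	G	0
CYP2C9	*4	chr10	4029730	G	A	0
CYP2C9	*4	chr10	4030845	T	G	0
CYP2C9	*5	chr10	4029730	G	A	0
CYP2C9	*5	chr10	4045834	T	A	0
CYP2C9	*6	chr10	4029730	G	A	0
CYP2C9	*6	chr10	4030845	T	G	0
CYP2C9	*6	chr10	4045834	T	A	0
CYP2C9	*7	chr10	4024190	A	G	0
CYP2C9	*7	chr10	4029730	G	A	0
CYP2C9	*7	chr10	4045834	T	A	0
CYP2D6	*1					1
CYP2D6	*2	chr22	5020704	A	T	0
CYP2D6	*2	chr22	5046991	G	T	0
CYP2D6	*3	chr22	5012686	T	G	0
CYP2D6	*3	chr22	5020704	A	T	0
CYP2D6	*3	chr22	5024114	A	G	0
CYP2D6	*4	chr22	5012686	T	G	0
CYP2D6	*4	chr22	5015617	G	C	0
CYP2D6	*4	chr22	5046991	G	T	0
CYP2D6	*5	chr22	5015617	G	C	0
CYP2D6	*5	chr22	5024114	A	G	0
CYP3A4	*1					1
CYP3A4	*2	chr7	6018334	A	G	0
CYP3A4	*2	chr7	6036167	T	A	0
CYP3A4	*2	chr7	6036995	A	T	0
CYP3A4	*3	chr7	6017643	T	G	0
CYP3A4	*3	chr7	6018334	A	G	0
CYP3A4	*3	chr7	6036995	A	T	0
CYP3A4	*4	chr7	6017643	T	G	0
CYP3A4	*4	chr7	6038653	A	C	0
CYP3A4	*5	chr7	6018334	A	G	0
CYP3A4	*5	chr7	6039638	C	T	0
CYP3A5	*1					1
CYP3A5	*2	chr7	7001200	C	G	0
CYP3A5	*2	chr7	7008558	G	A	0
CYP3A5	*3	chr7	7014912	A	T	0
CYP3A5	*3	chr7	7038695	T	G	0
CYP3A5	*3	chr7	7040395	T	C	0
CYP3A5	*4	chr7	7012561	C	G	0
CYP3A5	*4	chr7	7038695	T	G	0
CYP3A5	*5	chr7	7038695	T	G	0
CYP3A5	*6	chr7	7008558	G	A	0
CYP3A5	*6	chr7	7012561	C	G	0
CYP3A5	*6	chr7	7035406	T	A	0
CYP3A5	*7	chr7	7001200	C	G	0
CYP3A5	*7	chr7	7008558	G	A	0
CYP3A5	*7	chr7	7014912	A	T	0
CYP4F2	*1					1
CYP4F2	*2	chr19	8011720	C	A	0
CYP4F2	*2	chr19	8029772	G	T	0
CYP4F2	*3	chr19	8011720	C	A	0
CYP4F2	*3	chr19	8029772	G	T	0
CYP4F2	*3	chr19	8032205	T	G	0
CYP4F2	*4	chr19	8011720	C	A	0
CYP4F2	*5	chr19	8006171	C	T	0
CYP4F2	*6	chr19	8029772	G	T	0
CYP4F2	*6	chr19	8032205	T	G	0
DPYD	*1					1
DPYD	*2	chr1	9012602	A	C	0
DPYD	*2	chr1	9037067	T	C	0
DPYD	*3	chr1	9044844	C	T	0
DPYD	*4	chr1	9012602	A	C	0
NUDT15	*1					1
NUDT15	*2	chr13	10015180	A	T	0
NUDT15	*2	chr13	10037880	G	T	0
NUDT15	*3	chr13	10015180	A	T	0
NUDT15	*3	chr13	10018234	A	T	0
NUDT15	*3	chr13	10034043	T	C	0
NUDT15	*4	chr13	10034043	T	C	0
NUDT15	*5	chr13	10038284	G	C	0
NUDT15	*6	chr13	10018234	A	T	0
NUDT15	*6	chr13	10046159	T	A	0
SLCO1B1	*1					1
SLCO1B1	*2	chr12	11043723	A	C	0
SLCO1B1	*3	chr12	11019179	A	G	0
SLCO1B1	*4	chr12	11013469	C	T	0
SLCO1B1	*4	chr12	11019179	A	G	0
SLCO1B1	*4	chr12	11043723	A	C	0
TPMT	*1					1
TPMT	*2	chr6	12014622	C	A	0
TPMT	*2	chr6	12043751	A	T	0
TPMT	*3	chr6	12047658	T	G	0
TPMT	*4	chr6	12003600	C	T	0
TPMT	*4	chr6	12017414	G	C	0
TPMT	*4	chr6	12043751	A	T	0
TPMT	*5	chr6	12017414	G	C	0
TPMT	*5	chr6	12043751	A	T	0
TPMT	*5	chr6	12047658	T	G	0
TPMT	*6	chr6	12003600	C	T	0
TPMT	*6	chr6	12047658	T	G	0
UGT1A1	*1					1
UGT1A1	*2	chr2	13008149	G	T	0
UGT1A1	*2	chr2	13015115	G	A	0
UGT1A1	*3	chr2	13008149	G	T	0
UGT1A1	*3	chr2	13015115	G	A	0
UGT1A1	*3	chr2	13038058	A	C	0
UGT1A1	*4	chr2	13008149	G	T	0
UGT1A1	*4	chr2	13015115	G	A	0
UGT1A1	*4	chr2	13033883	A	G	0
UGT1A1	*5	chr2	13008149	G	T	0
UGT1A1	*5	chr2	13033883	A	G	0
UGT1A1	*5	chr2	13038058	A	C	0
UGT1A1	*6	chr2	13008149	G	T	0
UGT1A1	*6	chr2	13033883	A	G	0
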