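#format=pgxkb-1 build=GRCh38
gene	rsid	chromosome	position	ref	alt
VKORC1	rs9923231	chr16	31096368	C	T
ABCG2	rs2231142	chr4	88131171	G	T
IFNL3	rs12979860	chr19	39248147	C	T
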