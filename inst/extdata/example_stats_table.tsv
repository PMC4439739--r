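# hand-authored 3-bait x 5-prey example stats table
bait	prey	apsm	replicates
MIC19	MIC25	4	2
MIC19	MIC60	12	2
MIC19	QIL1	3	1
MIC19	SAMM50	5	2
MIC19	TMEM11	2	1
MIC60	MIC25	6	2
MIC60	MIC60	20	2
MIC60	QIL1	7	2
MIC60	SAMM50	9	2
MIC60	TMEM11	1	1
MTX2	MIC25	2	1
MTX2	MIC60	8	2
MTX2	QIL1	2.5	2
MTX2	SAMM50	14	2
MTX2	TMEM11	3	2
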