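drug	abbrev	fold_induction	nfkb_delay_min	pct_dead	pct_dead_tnf	pct_increase
Troglitazone	TGZ	1.3	2	1.1	2.6	1.5
Isoniazid	INH	1.0	2	2.8	3.3	0.5
Ofloxacin	OFX	1.1	8	2.3	3.2	0.9
Simvastatin	SN	1.1	2	2.5	3.6	1.1
Naproxen	NPX	1.8	4	2.1	2.3	0.2
Methotrexate	MTX	3.3	9	1.9	1.9	0
Amiodarone	AMI	1.9	22	5.8	9.0	3.2
Acetaminophen	APAP	4.0	4	2.5	2.5	0
3'-Hydroxyacetanilide	AMAP	4.0	4	3.1	3.4	0.3
Nitrofurantoin	NTF	4.6	29	2.9	3.6	0.7
Nefazodone	NFZ	4.8	22	3.5	6.8	3.3
Clozapine	CLZ	4.6	12	4.0	7.7	3.7
Carbamazepine	CBZ	4.1	20	3.9	22.5	18.6
Diclofenac	DCF	6.7	26	4.5	14.2	9.7
Ketoconazole	KTZ	8.3	26	5.0	8.1	3.1
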