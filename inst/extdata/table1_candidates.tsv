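gene	z_score	annotation_symbol	secondary_outcome
Cdk12	16.45	CG7597	Yes
Sk1	15.27	CG1747	Not checked
CG13369	13.17	CG13369	Not checked
fs(1)h	10.72	CG2252	Not checked
S6KL	10.62	CG7001	No
polo	9.75	CG12306	Yes
awd	9.7	CG2210	Not checked
dap	8.49	CG1772	Not checked
cv-2	8.48	CG15671	Not checked
Cdk1	8.08	CG5363	Yes
Drak	8.06	CG32666	No
BubR1	7.93	CG7838	Yes
aurB	7.39	CG6620	Yes
Ac78C	7.37	CG10564	Not checked
Not1	7.32	CG34407	Not checked
Sik2	7.17	CG4290	No
Cdk2	7.13	CG10498	Yes
CycE	6.96	CG3938	Not checked
Cdk5alpha	6.63	CG5387	Not checked
Taf1	6.55	CG17603	Not checked
Dsor1	6.55	CG15793	Not checked
Argk	6.51	CG32031	Not checked
ball	6.44	CG6386	Yes
Cdk4	6.32	CG5072	Yes
wit	6.28	CG10776	Yes
hipk	6.27	CG17090	No
sktl	6.15	CG9985	Not checked
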