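symbol	public_id	direction	mean_fc	sem_fc
ABCC13	NR_003087	down	0.42	0.03
ABI3BP	NM_015429	down	0.33	0.03
ACSL6	NM_001009185	down	0.31	0.01
ANAPC1	XM_006712690	down	0.33	0.02
BCAT1	NM_001178091	down	0.43	0.04
C1orf64	NM_178840	down	0.43	0.03
CACNG6	NM_145814	down	0.39	0.02
CSGALNACT1	NM_001130518	down	0.45	0.03
CTSC	NM_001114173	down	0.39	0.02
CYB5R3	NM_000398	down	0.48	0.04
DMD	NM_007868	down	0.37	0.02
ERH	NM_004450	down	0.38	0.02
F11R	NM_016946	down	0.46	0.02
FKBP9	NM_007270	down	0.49	0.06
FZD1	NM_003505	down	0.47	0.03
GDF5	NM_000557	down	0.44	0.03
GLRX5	NM_016417	down	0.46	0.04
HBA2	NM_000517	down	0.49	0.03
MCART3P	NR_026540	down	0.43	0.03
STRADB	NM_001206864	down	0.43	0.03
ZIC5	NM_033132	down	0.36	0.02
ATR	NM_001184	up	2.84	0.27
BIRC3	NM_001165	up	4.26	0.35
COL1A1	NM_000088	up	2.44	0.44
CD3G	NM_000073	up	3.06	0.25
EYA4	NM_001301012	up	3.77	0.53
FEM1A	NM_018708	up	2.68	0.49
FBXO15	NM_001142958	up	2.59	0.18
FGFR1OP2	NM_001171887	up	3.19	0.24
KRR1	NM_007043	up	2.25	0.19
OPTN	NM_001008211	up	2.01	0.14
PDE8B	XM_005248623	up	2.79	0.16
RMND5A	NM_0022780	up	2.90	0.43
SIGLEC8	NM_014442	up	2.49	0.29
SLC14A1	NM_001128588	up	2.47	0.22
SPATA22	NM_001170695	up	2.06	0.21
SSBP1	NM_001256510	up	3.12	0.25
TNFSF11	NM_003701	up	3.30	0.53
TTC25	NM_031421	up	2.52	0.15
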