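table	row	a	b	c	d	or_numerator	chi2_printed	chi2_convention	p_printed	p_method	or_printed	ci_low_printed	ci_high_printed	or_ok	ci_ok	note
grade_signs	phalanges_tuberositas	23	7	47	3	row2	3.688	yates	0.055	chi2	4.768	1.13	20.15	TRUE	TRUE	.
grade_signs	brachydactylia	3	27	49	1	row2	63.82	pearson	0.0001	chi2	441.0	43.7	4449	TRUE	TRUE	.
grade_signs	deformity_elbow	23	7	47	3	row2	3.688	yates	0.055	chi2	4.768	1.13	20.15	TRUE	TRUE	.
grade_signs	deformity_knee	11	19	35	15	row2	8.525	pearson	0.004	chi2	4.030	1.54	10.50	TRUE	TRUE	.
grade_signs	dyskinesia_wrist	22	8	46	4	row2	3.765	yates	0.052	chi2	4.182	1.13	15.39	TRUE	TRUE	.
grade_signs	dyskinesia_elbow	24	6	49	1	row2	5.521	yates	0.019	chi2	12.25	1.39	107.5	TRUE	TRUE	.
grade_signs	dyskinesia_shoulder	1	29	11	39	row2	3.765	yates	0.052	chi2	8.179	0.99	66.98	TRUE	TRUE	.
grade_signs	dyskinesia_knee	11	19	40	10	row2	15.23	pearson	0.0001	chi2	6.909	2.50	19.07	TRUE	TRUE	.
grade_signs	dyskinesia_ankle	26	4	48	2	row2	1.201	yates	0.273	chi2	3.692	0.63	21.53	TRUE	TRUE	.
grade_signs	fracture	2	28	6	44	row2	0.148	yates	0.700	chi2	1.909	0.36	10.13	TRUE	TRUE	.
grade_signs	blurred_vision	18	12	41	9	row2	4.688	pearson	0.030	chi2	3.037	1.08	8.479	TRUE	TRUE	.
grade_signs	hearing_disorder	13	17	19	31	row2	0.222	pearson	0.637	chi2	0.081	0.32	2.012	FALSE	TRUE	printed_or_typo_for_0.801
grade_signs	diarrhea	7	23	4	46	row2	3.717	pearson	0.054	chi2	0.286	0.07	1.077	TRUE	TRUE	.
grade_signs	astriction	2	28	0	50	row2	NA	none	0.138	fisher_one_sided	0.933	0.84	1.027	FALSE	FALSE	zero_cell_or_not_reproducible
grade_signs	senile_wart	7	23	10	40	row2	0.124	pearson	0.724	chi2	0.821	0.27	2.452	TRUE	TRUE	.
grade_signs	decayed_tooth	28	2	39	11	row2	2.210	yates	0.137	chi2	0.253	0.05	1.233	TRUE	TRUE	.
grade_signs	smoke	8	22	12	38	row2	0.071	pearson	0.790	chi2	0.868	0.31	2.450	TRUE	TRUE	.
grade_signs	alcohol	0	30	4	46	row2	NA	none	0.291	fisher_doubling	1.087	1.01	1.180	FALSE	FALSE	zero_cell_or_not_reproducible
grade_signs	family_kbd	10	20	34	16	row2	9.104	pearson	0.003	chi2	4.250	1.62	11.14	TRUE	TRUE	.
grade_genes	ATR	3	27	33	17	row2	23.76	pearson	0.001	chi2	17.4	4.62	65.96	TRUE	TRUE	.
grade_genes	CSGALNACT1	8	22	48	2	row2	42.92	pearson	0.001	chi2	66.0	12.93	336.71	TRUE	TRUE	.
grade_genes	CTSC	8	22	49	1	row2	46.57	pearson	0.001	chi2	134.7	15.87	1143.71	TRUE	TRUE	.
grade_genes	COL1A1	9	21	48	2	row2	39.87	pearson	0.001	chi2	56.0	11.13	281.76	TRUE	TRUE	.
grade_genes	FZD1	9	21	49	1	row2	43.48	pearson	0.001	chi2	114.3	13.61	960.45	TRUE	TRUE	.
grade_genes	GDF5	9	21	49	1	row2	43.48	pearson	0.001	chi2	114.3	13.61	960.45	TRUE	TRUE	.
grade_genes	SLC14A1	1	29	33	17	row2	30.13	pearson	0.001	chi2	56.2	7.05	449.51	TRUE	TRUE	.
grade_genes	SSBP1	9	21	48	2	row2	39.87	pearson	0.001	chi2	56.0	11.13	281.76	TRUE	TRUE	.
grade_genes	TNFSF11	1	29	32	18	row2	28.47	pearson	0.001	chi2	51.5	6.47	410.79	TRUE	TRUE	.
tuberositas_genes	ATR	35	1	35	9	row1	5.65	pearson	0.041	chi2	9.0	1.08	74.86	TRUE	TRUE	.
tuberositas_genes	CSGALNACT1	18	0	52	10	row1	3.31	pearson	0.157	chi2	NA	NA	NA	FALSE	FALSE	zero_cell
tuberositas_genes	COL1A1	54	2	16	8	row1	13.61	pearson	0.001	chi2	13.5	2.61	70.04	TRUE	TRUE	.
tuberositas_genes	CTSC	55	2	15	8	row1	14.65	pearson	0.001	chi2	14.6	2.81	76.47	TRUE	TRUE	.
tuberositas_genes	FZD1	56	2	14	8	row1	15.79	pearson	0.001	chi2	16.0	3.05	83.85	TRUE	TRUE	.
tuberositas_genes	GDF5	56	2	14	8	row1	15.79	pearson	0.001	chi2	16.0	3.05	83.85	TRUE	TRUE	.
tuberositas_genes	SLC14A1	51	3	19	7	row1	2.36	inconsistent	0.231	chi2	3.3	0.66	17.00	FALSE	FALSE	printed_stats_match_tnfsf11_counts
tuberositas_genes	TNFSF11	32	2	38	8	row1	11.29	inconsistent	0.003	chi2	9.3	2.13	40.75	FALSE	FALSE	printed_stats_inconsistent_with_counts
tuberositas_genes	SSBP1	31	2	39	8	row1	2.13	pearson	0.144	chi2	3.2	0.62	16.06	TRUE	TRUE	.
brachydactylia_genes	ATR	33	3	19	25	row1	20.46	pearson	0.001	chi2	14.4	3.85	54.39	TRUE	TRUE	.
brachydactylia_genes	COL1A1	12	6	40	22	row1	0.028	pearson	0.866	chi2	1.1	0.36	3.33	TRUE	TRUE	.
brachydactylia_genes	CSGALNACT1	49	7	3	21	row1	41.53	pearson	0.001	chi2	49.0	11.54	208.03	TRUE	TRUE	.
brachydactylia_genes	CTSC	50	7	2	21	row1	44.98	pearson	0.001	chi2	75.0	14.37	391.32	TRUE	TRUE	.
brachydactylia_genes	FZD1	50	8	2	20	row1	41.69	pearson	0.001	chi2	62.5	12.19	320.25	TRUE	TRUE	.
brachydactylia_genes	GDF5	50	8	2	20	row1	41.69	pearson	0.001	chi2	62.5	12.19	320.25	TRUE	TRUE	.
brachydactylia_genes	SLC14A1	32	2	20	26	row1	22.03	pearson	0.001	chi2	20.8	4.44	97.31	TRUE	TRUE	.
brachydactylia_genes	SSBP1	50	9	2	19	row1	38.52	pearson	0.001	chi2	52.7	10.43	266.86	TRUE	TRUE	.
brachydactylia_genes	TNFSF11	31	2	21	26	row1	20.67	pearson	0.001	chi2	19.1	4.11	89.62	TRUE	TRUE	.
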