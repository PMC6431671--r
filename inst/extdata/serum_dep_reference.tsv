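# itraqnet table schema=protein_summary v1
# Published serum differential-protein summary: 13 proteins called in a
# 30-patient nasopharyngeal-carcinoma vs pooled-healthy-control iTRAQ study.
# mean_ratio is the NPC/control protein ratio; protein_score is the unused
# protein score from the spectral search; n_peptides counts distinct peptides.
protein_acc	description	coverage_pct	mean_ratio	p_value	n_peptides	protein_score
P01009	Alpha-1-antitrypsin	45.61	2.02	0.034	22	37.04
P01857	Ig gamma-1 chain C region	53.51	3.32	0.001	20	26.76
P01859	Ig gamma-2 chain C region	39.83	0.51	6.26E-08	16	12.11
P04114	Apolipoprotein B-100	3.37	1.4	0.005	10	21.8
P02763	Alpha-1-acid glycoprotein 1	29.85	2.32	3.68E-04	6	10.2
Q14624	Inter-alpha-trypsin inhibitor heavy chain H4	4.44	1.4	1.75E-04	3	7.42
P19823	Inter-alpha-trypsin inhibitor heavy chain H2	6.413	0.76	7.00E-03	3	7.55
P01008	Antithrombin III	7.83	3.34	2.59E-04	3	6.58
P05155	Plasma protease C1 inhibitor	11.66	1.54	1.62E-04	3	7.01
P01023	Alpha-2-macroglobulin	28.14	0.53	7.73E-10	27	53.11
P00738	Haptoglobin	35.22	1.39	1.20E-02	12	21.41
P02647	Apolipoprotein A-I	45.75	0.57	2.17E-08	14	25.64
P04196	Histidine-rich glycoprotein	10.52	0.74	7.97E-07	3	6.52
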