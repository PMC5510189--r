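transcript_id	gene	chromosome	mean_nonrecurrent	mean_metlethal	difference	fold_change	auc	pauc	p_ttest	q_value
ILMN_1748538	ALDH1A2	15	11.44	10.39	-1.05	0.48	0.75	0.0135	1.60e-4	3.09e-3
ILMN_1786125	CCNA2	4	10.99	11.29	0.30	1.23	0.61	0.0078	6.91e-2	1.58e-1
ILMN_1716279	CENPE	4	7.93	8.27	0.34	1.26	0.62	0.0046	4.42e-2	1.31e-1
ILMN_1694584	CLTCL1	22	7.84	8.44	0.60	1.52	0.72	0.0089	7.85e-4	7.53e-3
ILMN_1673843	CST2	20	8.71	9.37	0.66	1.58	0.65	0.0029	5.19e-2	1.33e-1
ILMN_1708107	DPT	1	10.74	9.85	-0.89	0.54	0.70	0.0066	4.10e-3	2.46e-2
ILMN_1700541	FBLN1	22	13.81	13.30	-0.51	0.70	0.72	0.0051	2.49e-3	1.70e-2
ILMN_1756358	FBXO36	2	11.20	11.50	0.31	1.24	0.72	0.0010	8.79e-2	1.83e-1
ILMN_2406084	ITGA11	15	9.56	10.24	0.68	1.61	0.69	0.0075	1.10e-2	5.84e-2
ILMN_1702738	KLC3	19	7.32	7.67	0.35	1.27	0.67	0.0154	2.23e-3	1.70e-2
ILMN_1661895	PI15	8	12.48	11.99	-0.49	0.71	0.68	0.0002	3.16e-2	1.08e-1
ILMN_1734810	PJA1	X	9.40	9.06	-0.34	0.79	0.64	0.0051	5.26e-2	1.33e-1
ILMN_1737025	PLCL2	3	10.45	9.92	-0.53	0.69	0.62	0.0052	4.12e-2	1.31e-1
ILMN_1794490	PNMAL1	19	8.99	8.52	-0.47	0.72	0.64	0.0066	1.62e-2	7.06e-2
ILMN_1739393	SELE	1	9.88	9.29	-0.58	0.67	0.64	0.0024	4.65e-2	1.31e-1
ILMN_1730295	SIGLEC8	19	8.18	8.47	0.29	1.22	0.61	0.0069	5.75e-2	1.38e-1
ILMN_2086105	SPRY4	5	12.24	12.68	0.43	1.35	0.68	0.0079	1.53e-2	7.06e-2
ILMN_1788895	SRD5A2	2	11.26	10.54	-0.72	0.61	0.78	0.0021	1.93e-4	3.09e-3
ILMN_1704154	TNFRSF19	13	12.56	12.14	-0.42	0.75	0.65	0.0016	8.45e-2	1.83e-1
ILMN_2089875	TNFSF4	1	8.52	8.95	0.43	1.34	0.66	0.0149	2.36e-2	8.96e-2
ILMN_1796949	TPX2	20	8.53	9.13	0.60	1.52	0.65	0.0044	2.43e-2	8.96e-2
ILMN_1748124	TSC22D3	X	11.64	11.12	-0.53	0.69	0.77	0.0073	3.15e-5	1.51e-3
ILMN_1656192	ZNF704	8	11.33	11.73	0.40	1.32	0.73	0.0067	6.78e-4	7.53e-3
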