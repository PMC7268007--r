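patient_id	gender	age	education_level	handedness	ez_laterality	hs	vol_hippo_r	vol_hippo_l	age_onset	epilepsy_duration	seizure_frequency	n_aeds	iq	ef_total	tmt_a	tmt_b_a	stroop	naming	semantic_fluency	phono_fluency	vci	ami	vmi
Pat01	F	32	2	R (+80%)	Left	Yes	3.27	2.69	20	12	15–30	4	100	-0.08	0.35	-1.16	0.58	-1.30	-1.76	-2.02	104	97	108
Pat02	M	30	3	L (−100%)	Left	No	4.60	4.50	23	7	<10	4	114	-0.13	0.57	-0.11	-0.85	-1.30	-0.64	-0.97	120	97	110
Pat03	M	32	1	L (−60%)	Left	Yes	4.26	2.88	23	9	15–30	4	85	-0.24	-0.53	0.07	-0.25	-1.46	-2.54	-0.92	77	68	93
Pat04	F	48	2	R (+70%)	Left	Yes	3.41	3.11	5	43	<10	2	120	-0.06	-0.08	0.05	-0.15	-0.95	-2.64	-1.87	100	83	97
Pat05	F	29	2	R (+70%)	Left	Yes	4.27	3.95	11	18	10–15	3	106	0.24	0.89	0.28	-0.45	-1.50	-1.02	-1.45	102	88	96
Pat06	F	49	2	R (+70%)	Left	No	4.60	4.33	13	36	10	3	90	0.15	0.89	0.56	-1.00	-0.39	-1.60	-1.22	88	88	101
Pat07	H	23	2	R (+90%)	Left	No	4.18	4.00	11	12	10–15	3	127	0.02	1.30	-0.67	-0.58	-1.60	-1.16	-1.86	126	104	104
Pat08	F	25	1	R (+80%)	Left	Yes	3.36	2.77	8	17	20	3	110	0.25	0.40	0.32	0.02	-1.65	-2.02	-1.77	110	91	120
Pat09	M	27	1	R (+80%)	Left	No	3.39	3.18	21	6	15	2	99	-0.52	-0.02	-0.25	-1.30	-1.90	-1.20	-1.00	100	100	83
Pat10	F	43	3	R (+90%)	Left	Yes	4.19	2.77	13	30	20–30	3	102	0.27	0.50	-0.20	0.50	-0.98	-1.25	-1.55	108	96	97
Pat11	F	37	2	R (+100%)	Left	No	3.88	3.91	6	31	15	3	105	0.01	0.45	-0.25	-0.16	-0.30	-0.65	-1.09	100	88	102
Pat12	M	24	2	R (+100%)	Left	No	4.37	4.30	23	1	>30	2	108	-0.37	0.25	0.14	-1.50	-1.30	0.64	0.68	108	101	91
Pat13	M	38	2	R (+80%)	Left	Yes	3.49	2.50	6	32	10–20	2	102	0.33	0.80	0.45	-0.27	-1.08	-1.78	-1.33	98	79	98
Pat14	F	35	2	L (−60%)	Left	No	4.10	3.93	10	25	10–15	2	114	0.61	1.10	0.65	0.08	-1.30	-0.79	-1.05	114	102	100
Pat15	M	45	3	L (−60%)	Left	Yes	3.46	1.96	40	5	15–20	2	84	0.10	0.65	0.45	-0.80	-1.20	-1.85	-0.96	100	85	98
Pat16	M	54	1	R (+70%)	Left	Yes	3.98	3.96	22	31	20	2	107	0.12	0.25	0.12	-0.02	-1.50	-1.69	-0.78	94	100	122
Pat17	F	43	3	R (+100%)	Left	No	5.24	4.75	12	31	<10	2	102	-0.20	0.20	0.20	-1.00	0.96	0.62	0.52	104	78	74
Pat18	M	24	3	L (−80%)	Left	Yes	2.35	2.04	16	9	15	3	100	0.91	1.21	1.03	0.50	-2.00	-0.97	-1.92	94	46	91
Pat19	F	26	3	R (+100%)	Left	Yes	3.69	3.13	13	13	15–20	2	81	-0.11	-0.35	-0.12	0.15	-2.30	-1.89	-1.52	92	84	100
Pat20	F	39	3	R (+90%)	Right	Yes	4.12	5.10	19	20	>30	3	107	0.05	0.67	0.22	-0.75	-0.82	0.25	-0.25	107	100	88
Pat21	F	52	3	L (−40%)	Right	No	4.35	4.22	15	37	10–15	2	90	-0.29	0.35	-0.26	-0.97	-0.03	-0.70	1.20	94	96	98
Pat22	M	30	1	R (+80%)	Right	Yes	2.07	4.12	10	20	15	2	84	0.24	0.34	0.30	0.09	-3.25	1.58	-0.23	83	92	80
Pat23	F	32	1	R (+100%)	Right	Yes	1.81	2.98	16	16	15	2	84	0.46	0.70	0.50	0.19	-3.43	0.90	-0.60	84	84	82
Pat24	M	35	3	R (+100%)	Right	Yes	3.43	4.12	14	21	<10	2	112	-0.07	0.68	0.38	-1.28	-2.30	1.76	-0.76	114	99	90
Pat25	M	22	1	R (+100%)	Right	Yes	3.71	5.10	13	9	15–20	3	98	-0.27	-0.21	-1.25	0.65	-1.20	-0.50	1.80	98	88	76
Pat26	M	39	2	R (+100%)	Right	No	4.18	4.24	7	32	20	2	110	-0.06	0.10	-0.05	-0.23	0.32	1.30	1.25	112	97	95
Pat27	F	46	1	R (+100%)	Right	Yes	4.07	4.39	8	38	15	4	106	0.53	0.41	0.16	1.01	-0.55	0.56	0.33	108	96	76
Pat28	F	25	1	R (+90%)	Right	No	4.19	4.14	13	12	15	4	102	-0.98	-0.80	-1.20	-0.95	-0.52	1.67	-0.56	98	102	85
Pat29	M	37	1	R (+80%)	Right	Yes	3.90	4.58	27	10	10–15	2	100	0.63	0.30	0.56	1.02	0.65	1.40	0.45	104	100	84
Pat30	M	52	3	R (+100%)	Right	No	3.59	3.82	39	13	10	2	122	0.44	1.14	0.28	-0.10	0.37	1.42	-0.30	128	104	100
Pat31	F	43	2	R (+100%)	Right	No	3.13	3.23	17	26	15	2	98	-0.29	0.57	-0.15	-1.28	0.32	-0.23	0.56	98	92	92
Pat32	F	31	3	R (+100%)	Right	No	3.33	3.50	3	28	10	3	116	0.65	0.43	0.37	1.16	0.70	0.95	0.31	122	116	102
Pat33	F	19	1	L (−100%)	Right	No	3.48	3.48	12	7	20	3	88	0.22	0.12	0.25	0.30	-0.39	1.37	-0.40	81	110	78
Pat34	F	42	2	L (−40%)	Right	Yes	3.30	3.43	6	36	10	3	104	0.63	0.66	0.20	1.02	0.60	1.02	1.16	102	98	100
Pat35	F	36	2	R (+90%)	Right	No	3.80	4.08	19	17	10–15	4	106	-0.48	-0.30	-0.55	-0.60	0.32	1.23	1.08	100	96	90
Pat36	M	30	2	R (+80%)	Right	Yes	2.24	3.71	24	6	10–15	2	96	-0.07	0.70	0.50	-1.40	-0.39	0.35	-0.19	98	95	81
Pat37	M	45	3	L (−100%)	Right	Yes	3.38	4.01	32	13	20–30	2	119	0.00	0.50	-0.09	-0.40	-2.30	0.92	-1.33	114	102	82
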