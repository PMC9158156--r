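family_id	n_patients	onset_age	pv_gene	vus_gene	apoe_risk	prs	has_e44	flags
1	2	57.0	APP		0.24	-0.49	FALSE	PV
2	2	48.0	GRN		0.24	0.61	FALSE	PV,PRS
3	2	69.5	PSEN1		0.01	-0.26	FALSE	PV
4	2	56.0	PSEN1		-0.36	-0.08	FALSE	PV
5	2	64.5	PSEN1		-0.36	-0.33	FALSE	PV
6	2	49.0	PSEN1		0.84	0.06	FALSE	PV
7	2	59.0	PSEN1		0.24	-0.23	FALSE	PV
8	2	57.5	SORL1		1.44	0.47	TRUE	PV,APOE,PRS
9	2	65.0		ABCA7	2.04	0.20	TRUE	VUS,APOE
10	2	64.0		BIN1	1.44	0.02	TRUE	VUS,APOE
11	2	69.5		CR1	1.44	0.37	TRUE	VUS,APOE
12	2	69.5		FERMT2	2.04	0.20	TRUE	VUS,APOE
13	2	69.0		MADD	2.04	-0.02	TRUE	VUS,APOE
14	2	63.0		PRNP	0.24	0.12	FALSE	VUS
15	2	59.5		SORL1	1.44	0.15	TRUE	VUS,APOE
16	2	73.0		SQSTM1	0.84	0.42	FALSE	VUS
17	2	68.0			1.44	0.60	TRUE	APOE,PRS
18	4	70.3			2.04	0.56	TRUE	APOE,PRS
19	2	62.5			1.44	-0.17	TRUE	APOE
20	2	68.5			1.44	-0.14	TRUE	APOE
21	2	62.0			2.04	0.32	TRUE	APOE
22	2	56.0			2.04	-0.15	TRUE	APOE
23	2	65.0			1.44	-0.04	TRUE	APOE
24	2	68.0			1.44	-0.08	TRUE	APOE
25	3	56.7			1.64	0.41	TRUE	APOE
26	3	59.0			1.24	-0.30	TRUE	APOE
27	2	59.0			2.04	0.01	TRUE	APOE
28	2	67.5			-0.36	-0.18	FALSE
29	3	63.5			0.44	-0.33	FALSE
30	2	64.9			-0.36	-0.10	FALSE
31	2	73.0			0.84	-0.01	FALSE
32	2	63.5			-0.36	-0.19	FALSE
33	2	63.5			0.84	0.19	FALSE
34	2	59.5			0.24	0.04	FALSE
35	2	69.0			0.24	-0.15	FALSE
36	2	59.0			0.84	0.19	FALSE
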