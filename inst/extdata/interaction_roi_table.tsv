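snp_id	gene	allele	label	abbrev	hemisphere	x	y	z	cluster_size_mm3	peak_F	pass_S	pass_SG
rs2230806	ABCA1	AG	Middle Occipital Gyrus	L.MOG	L	-21	-102	9	2214	12.70	TRUE	FALSE
rs2230806	ABCA1	AG	Middle Frontal Gyrus	L.MFG	L	-15	30	33	2241	9.96	TRUE	FALSE
rs2230806	ABCA1	AG	Vermis_4_5	Vermis45	vermis	0	-57	0	1539	9.95	TRUE	FALSE
rs7412	APOE	CT	Inferior Frontal Gyrus	L.IFG	L	-42	27	24	2079	19.15	TRUE	FALSE
rs7412	APOE	CT	Middle Temporal Gyrus	L.MTG	L	-60	-33	-15	2025	15.59	TRUE	FALSE
rs7412	APOE	CT	Insula	R.INS	R	33	-9	15	2403	14.79	TRUE	FALSE
rs7412	APOE	CT	Middle Cingulum Gyrus	R.MCG	R	15	-24	39	1809	14.40	TRUE	FALSE
rs429358	APOE	CT	Cerebellum Posterior Lobe	L.CRBL_Po	L	-36	-57	-33	2349	81.78	TRUE	TRUE
rs429358	APOE	CT	Superior Temporal Gyrus	R.STG	R	36	15	-36	1485	66.04	TRUE	TRUE
rs429358	APOE	CT	Anterior Cingulate Gyrus	L.ACG	L	-3	21	18	2538	38.42	TRUE	FALSE
rs429358	APOE	CT	Parahippocampal Gyrus	L.PHG	L	-12	-45	-3	1998	31.11	TRUE	FALSE
rs440446	APOE	CG	Precuneus	R.PCUN	R	15	-48	51	2754	21.37	TRUE	FALSE
rs440446	APOE	CG	Cerebellum Anterior Lobe	L.CRBL_Ant	L	-21	-51	-36	2133	21.34	TRUE	FALSE
rs440446	APOE	CG	Cerebellum Posterior Lobe	R.CRBL_Po	R	21	-57	-39	3159	17.91	TRUE	FALSE
rs440446	APOE	CG	Middle Temporal Gyrus	L.MTG	L	-57	-66	9	1431	15.37	TRUE	FALSE
rs4417181	CH25H	CT	Middle Frontal Gyrus	R.MFG	R	39	30	15	1809	15.37	TRUE	FALSE
rs754203	CYP1	CT	Inferior Frontal Gyrus	R.IFG	R	30	27	-15	2916	17.80	TRUE	FALSE
rs754203	CYP1	CT	Parahippocampal Gyrus	R.PHG	R	36	-12	-27	2079	15.94	TRUE	FALSE
rs7157609	CYP1	AC	Inferior Frontal Gyrus	R.IFG	R	30	27	-15	2565	15.00	TRUE	FALSE
rs7157609	CYP1	AC	Parahippocampal Gyrus	R.PHG	R	33	-12	-27	2106	14.87	TRUE	FALSE
rs1433099	LDLR	AG	Medial Frontal Gyrus	R.MeFG	R	3	21	48	1296	16.18	TRUE	FALSE
rs2738444	LDLR	CT	Inferior Parietal Lobule	R.IPL	R	45	-36	42	5940	28.40	TRUE	TRUE
rs1799986	LRP1	CT	Inferior Temporal Gyrus	R.ITG	R	69	-27	-21	1620	16.63	TRUE	FALSE
rs5177	LRP8	CG	Middle Frontal Gyrus	R.MFG	R	48	9	39	3780	27.68	TRUE	FALSE
rs5177	LRP8	CG	Insula	R.INS	R	30	24	18	4698	18.91	TRUE	FALSE
rs5177	LRP8	CG	Precentral Gyrus	R.PreCG	R	36	-24	54	4779	17.88	TRUE	FALSE
rs5177	LRP8	CG	Medial Frontal Gyrus	B.MeFG	bilateral	-9	36	-15	4131	16.36	TRUE	FALSE
rs3737983	LRP8	CT	Superior Frontal Gyrus	R.SFG	R	18	36	51	1296	14.93	TRUE	FALSE
rs3820198	LRP8	GT	Putamen	L.Put	L	-30	6	3	3483	14.34	TRUE	FALSE
rs1801133	MTHFR	CT	Middle Occipital Gyrus	L.MOG	L	-24	-84	15	1404	8.49	TRUE	FALSE
rs3753526	SOAT1	CG	Inferior Frontal Gyrus	L.IFG	L	-39	27	3	2916	22.29	TRUE	FALSE
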