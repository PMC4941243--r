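snp_id	gene	allele	sim_maf
rs2230806	ABCA1	AG	0.42
rs7412	APOE	CT	0.08
rs405509	APOE	AC	0.45
rs429358	APOE	CT	0.15
rs440446	APOE	CG	0.36
rs769450	APOE	AG	0.48
rs4417181	CH25H	CT	0.33
rs7091822	CH25H	GT	0.22
rs17117126	CH25H	AG	0.12
rs2424577	CST3	AG	0.40
rs3827143	CST3	AG	0.19
rs754203	CYP1	CT	0.38
rs4900442	CYP1	CT	0.27
rs7157609	CYP1	AC	0.35
rs3758505	IDE	GT	0.44
rs4646954	IDE	AG	0.16
rs688	LDLR	CT	0.43
rs5925	LDLR	CT	0.41
rs1433099	LDLR	AG	0.30
rs2738444	LDLR	CT	0.18
rs11668477	LDLR	AG	0.24
rs12983082	LDLR	AC	0.21
rs1140648	LRP1	AG	0.34
rs1799986	LRP1	CT	0.14
rs2306692	LRP1	CT	0.11
rs5177	LRP8	CG	0.46
rs3737983	LRP8	CT	0.32
rs3820198	LRP8	GT	0.37
rs1801133	MTHFR	CT	0.39
rs2227564	PLAU	CT	0.28
rs1044925	SOAT1	AC	0.26
rs2862616	SOAT1	CT	0.23
rs3753526	SOAT1	CG	0.25
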