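probe_id	chrom	pos	region_label	beta_never	sd_never	beta_current	sd_current	coef	se	p	cis_meqtl
cg05951221	2	233284402	2q37.1	0.255	0.054	0.172	0.040	-1.380	0.108	1.28e-29	rs2853386
cg21566642	2	233284661	2q37.1	0.225	0.040	0.167	0.029	-1.347	0.122	1.87e-23	NA
cg23680900	15	75017924	CYP1A1	0.202	0.036	0.155	0.030	-1.198	0.118	2.96e-21	NA
cg14120703	9	139416102	NOTCH1	0.748	0.045	0.693	0.044	-1.172	0.118	1.44e-20	NA
cg26516004	15	75019376	CYP1A1	0.696	0.047	0.628	0.058	-1.258	0.126	1.95e-20	NA
cg10009577	15	75018150	CYP1A1	0.068	0.021	0.050	0.016	-0.810	0.090	2.48e-17	NA
cg01985595	6	136479501	PDE7B	0.961	0.025	0.936	0.032	-1.015	0.119	1.09e-15	NA
cg22418620	5	172072885	NEURL1B	0.832	0.049	0.765	0.057	-1.077	0.127	1.63e-15	rs57285944
cg23160522	15	75015787	CYP1A1	0.622	0.033	0.583	0.044	-0.991	0.122	1.33e-14	NA
cg03636183	19	17000585	F2RL3	0.506	0.040	0.473	0.038	-0.826	0.103	1.80e-14	NA
cg07992500	2	37896583	CDC42EP3	0.771	0.051	0.719	0.052	-1.087	0.141	1.88e-13	rs7595854
cg12531611	6	11212619	NEDD9	0.909	0.021	0.892	0.024	-0.855	0.120	1.12e-11	NA
cg03646542	5	172076155	NEURL1B	0.689	0.037	0.654	0.035	-0.880	0.133	1.87e-10	rs7715699
cg00353139	15	75017914	CYP1A1	0.034	0.013	0.022	0.010	-0.787	0.121	4.47e-10	rs11072498
cg21124714	11	72983097	P2RY6	0.736	0.037	0.707	0.033	-0.874	0.136	5.15e-10	NA
cg01940273	2	233284934	2q37.1	0.334	0.045	0.302	0.044	-0.679	0.105	8.93e-10	NA
cg25648203	5	395444	AHRR	0.503	0.044	0.459	0.040	-0.825	0.132	1.30e-9	NA
cg20408276	2	38300586	CYP1B1	0.548	0.060	0.499	0.059	-0.781	0.125	1.61e-9	NA
cg20131897	12	52305332	ACVRL1	0.694	0.034	0.673	0.028	-0.693	0.116	5.61e-9	rs1700159
cg21611682	11	68138269	LRP5	0.370	0.041	0.336	0.035	-0.734	0.124	8.10e-9	NA
cg19405895	5	407315	AHRR	0.955	0.014	0.942	0.024	-0.768	0.128	8.38e-9	NA
cg05575921	5	373378	AHRR	0.713	0.044	0.682	0.039	-0.611	0.104	1.07e-8	rs7731963
cg13531977	9	112013420	EPB41L4B	0.807	0.035	0.833	0.029	0.831	0.140	1.14e-8	NA
cg00512031	4	5021976	CYTL1	0.880	0.026	0.855	0.028	-0.760	0.129	1.23e-8	chr4:5022470
cg25189904	1	68299493	GNG12	0.100	0.043	0.064	0.030	-0.771	0.131	1.48e-8	NA
cg00378510	19	2291020	LINGO3	0.217	0.059	0.181	0.053	-0.781	0.134	1.53e-8	rs12609156
cg11554391	5	321320	AHRR	0.065	0.019	0.048	0.014	-0.720	0.125	2.00e-8	NA
cg01802380	13	107865407	FAM155A	0.845	0.030	0.825	0.037	-0.737	0.133	5.69e-8	rs9520326
cg14179389	1	92947961	GFI1	0.083	0.030	0.063	0.028	-0.665	0.122	1.07e-7	NA
cg06644428	2	233284112	2q37.1	0.036	0.018	0.024	0.010	-0.704	0.130	1.61e-7	NA
cg12081267	2	98486185	TMEM131	0.878	0.038	0.858	0.035	-0.650	0.122	1.97e-7	NA
cg02162897	2	38300537	CYP1B1	0.567	0.060	0.520	0.061	-0.674	0.127	2.89e-7	NA
cg11555067	2	99081350	INPP4A	0.725	0.047	0.700	0.046	-0.717	0.138	3.18e-7	rs3754893
cg04134818	5	148998446	FLJ41603	0.153	0.026	0.133	0.025	-0.690	0.132	3.26e-7	rs11950259
cg03976650	13	77456505	KCTD12	0.667	0.061	0.612	0.067	-0.754	0.143	3.56e-7	NA
cg22851561	14	74214183	C14orf43	0.422	0.041	0.390	0.040	-0.634	0.121	3.92e-7	NA
cg10376100	1	236017278	LYST;MIR1537	0.923	0.036	0.947	0.030	0.615	0.117	4.03e-7	NA
cg04063216	2	14772482	FAM84A	0.071	0.016	0.075	0.019	0.441	0.085	4.39e-7	NA
cg16320419	3	5025570	BHLHE40	0.352	0.052	0.315	0.048	-0.699	0.135	4.88e-7	NA
cg04135110	5	346695	AHRR	0.339	0.061	0.384	0.065	0.699	0.137	5.34e-7	rs2672748
cg20109054	6	31804109	C6orf48;SNORD52	0.091	0.026	0.072	0.023	-0.659	0.130	7.85e-7	rs3828922
cg16721845	11	68518800	MTL5	0.018	0.008	0.014	0.007	-0.530	0.106	8.37e-7	NA
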