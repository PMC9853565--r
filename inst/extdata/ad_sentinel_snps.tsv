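gene_locus	chrom	rsid	pos	pval_overall	gwas_study	closest_peak_distance	peak_start	peak_end	log2fc_NEUN	log2fc_PU1	log2fc_OEG
APOE	chr19	rs41289512	45351516	5.79E-276	Jansen	0	45347500	45352552	-0.599051558	0.702466985	-0.103402899
BIN1	chr2	rs6733839	127892810	2.10E-44	Kunkle	0	127824833	127857093	-0.744462694	0.211415139	0.533064808
BIN1	chr2	rs4663105	127891427	3.38E-44	Jansen	0	127824833	127857093	-0.744462694	0.211415139	0.533064808
PICALM	chr11	rs3851179	85868640	6.00E-25	Kunkle	0	85865576	85869702	-2.003772477	1.175357699	0.828425616
CR1	chr1	rs4844610	207802552	3.60E-24	Kunkle	0	207800766	207803241	-1.496538907	0.411639699	1.084907206
CLU/PTK2B	chr8	rs9331896	27467686	4.60E-24	Kunkle	0	27464855	27473351	-0.146423136	-0.342092698	0.488530519
CLU/PTK2B	chr8	rs4236673	27464929	2.61E-19	Jansen	0	27464855	27473351	-0.146423136	-0.342092698	0.488530519
PICALM	chr11	rs867611	85776544	2.19E-18	Jansen	0	85773701	85782052	-0.878318768	0.59296884	0.285364043
TREM2	chr6	rs75932628	41129252	2.70E-15	Kunkle	0	41123195	41131918	-1.3555633	2.011559515	-0.655985632
CLU/PTK2B	chr8	rs73223431	27219987	6.30E-14	Kunkle	0	27216401	27226944	0.804019973	0.334689571	-1.138697236
SPI1	chr11	rs3740688	47380340	5.40E-13	Kunkle	0	47379638	47380774	0.036871997	0.607042966	-0.643907383
SORL1	chr11	rs11218343	121435587	2.90E-12	Kunkle	0	121434568	121439029	-0.360132993	0.8441546	-0.484011059
SORL1	chr11	rs11218343	121435587	1.09E-11	Jansen	0	121434568	121439029	-0.360132993	0.8441546	-0.484011059
HLA-DRB1	chr6	rs9271058	32575406	1.40E-11	Kunkle	0	32575148	32577842	-1.386968687	2.093033774	-0.706057504
EPHA1	chr7	rs7810606	143108158	3.59E-11	Jansen	0	143106905	143108283	-0.303851955	0.835592345	-0.531732978
ABCA7	chr19	rs111278892	1039323	7.93E-11	Jansen	0	1038908	1043234	-0.296373211	0.332547828	-0.036162888
HLA-DRB1	chr6	rs6931277	32583357	8.41E-11	Jansen	0	32582269	32584446	-1.301789562	1.992085151	-0.690289688
ADAMTS4	chr1	rs4575098	161155392	2.05E-10	Jansen	0	161148711	161156367	-0.549341105	0.511794299	0.037559007
CASS4	chr20	rs6014724	54998544	6.56E-10	Jansen	0	54994953	54999360	-0.82514278	1.586379997	-0.761227739
NYAP1	chr7	rs12539172	100091795	9.30E-10	Kunkle	0	100085037	100088295	0.016179468	-0.325104173	0.308936027
ADAM10	chr15	rs442495	59022615	1.31E-09	Jansen	0	59020947	59024537	-0.854287247	0.363816841	0.49048051
ECHDC3	chr10	rs7920721	11720308	2.30E-09	Kunkle	0	11714504	11720725	-0.443367527	1.535382419	-1.092004912
INPP5D	chr2	rs10933431	233981912	3.40E-09	Kunkle	0	233976966	233984034	-0.751579648	1.610757377	-0.859166938
CD33	chr19	rs3865444	51727962	6.34E-09	Jansen	0	51727712	51728032	0.09666484	1.050643064	-1.147304253
ACE	chr17	rs138190086	61538148	7.50E-09	Kunkle	0	61538112	61538580	-0.090757218	0.725122365	-0.634360388
ECHDC3	chr10	rs11257238	11717397	1.26E-08	Jansen	0	11714504	11720725	-0.443367527	1.535382419	-1.092004912
ALPK2	chr18	rs76726049	56189459	3.30E-08	Jansen	0	56193436	56194075	-0.772160797	1.372526359	-0.600361544
APH1B	chr15	rs117618017	63569902	3.35E-08	Jansen	0	63567370	63571899	-0.182293607	0.063658874	0.118647308
CASS4	chr20	rs6024870	54997568	3.50E-08	Kunkle	0	54994953	54999360	-0.82514278	1.586379997	-0.761227739
KAT8	chr16	rs59735493	31133100	3.98E-08	Jansen	0	31132717	31133297	0.769923745	-0.192635059	-0.577283985
BZRAP-AS1	chr17	rs2632516	56409089	9.66E-07	Jansen	0	56409045	56411269	-0.534067259	1.685675299	-1.151598432
INPP5D	chr2	rs10933431	233981912	8.92E+10	Jansen	0	233976966	233984034	-0.751579648	1.610757377	-0.859166938
ZCWPW1	chr7	rs1859788	99971834	2.22E-15	Jansen	74	99971908	99972977	-0.587916605	1.520171864	-0.932247137
MS4A2	chr11	rs7933202	59936926	1.90E-19	Kunkle	-121	59936521	59936805	0.349562941	0.908767826	-1.258327617
SLC24A4	chr14	rs12590654	92938855	1.65E-10	Jansen	222	92939077	92940753	0.076299566	1.166870187	-1.243161989
APOE	chr19	rs429358	45411941	NA	Kunkle	276	45412217	45412618	-0.685919297	0.70439705	-0.018472744
FERMT2	chr14	rs17125924	53391680	1.40E-09	Kunkle	-434	53390146	53391246	-0.835642458	0.288762577	0.546886874
SCIMP	chr17	rs113260531	5138980	9.16E-10	Jansen	-482	5135305	5138498	-0.82789803	1.691000283	-0.863092835
ABI3	chr17	rs28394864	47450775	1.87E-08	Jansen	-516	47449704	47450259	-1.416013571	0.750716835	0.665301832
SLC24A4	chr14	rs12881735	92932828	7.40E-09	Kunkle	886	92933714	92934206	-0.230512734	1.371875261	-1.141358708
EPHA1	chr7	rs10808026	143099133	1.30E-10	Kunkle	3136	143102269	143103054	-0.214105144	0.150370138	0.063740851
HESX1	chr3	rs184384746	57226150	1.24E+08	Jansen	4299	57230449	57230985	0.803339853	0.102926026	-0.906261534
ABCA7	chr19	rs3752246	1056492	3.10E-16	Kunkle	7116	1063608	1065445	-0.661452848	1.248270475	-0.586810045
CR1	chr1	rs2093760	207786828	1.10E-18	Jansen	-1966	207784517	207784862	-1.415642369	0.445194153	0.970451535
CD2AP	chr6	rs9473117	47431284	1.20E-10	Kunkle	-1984	47428686	47429300	-1.493938259	1.868936054	-0.37499374
MS4A6A	chr11	rs2081545	59958380	1.55E-15	Jansen	-2258	59955591	59956122	-1.745958809	2.242252117	-0.496290856
CD2AP	chr6	rs9381563	47432637	2.52E-10	Jansen	-3337	47428686	47429300	-1.493938259	1.868936054	-0.37499374
CNTNAP2	chr7	rs114360492	145950029	2.10E-09	Jansen	-17047	145931797	145932982	1.397706583	-0.880179139	-0.517521709
HS3ST1	chr4	rs7657553	11723235	0.051	Jansen	-18278	11704552	11704957	0.998279239	-0.566853392	-0.431422538
TREM2	chr6	rs187370608	40942196	1.45E-16	Jansen	21690	40963886	40965725	0.626190634	-0.352810161	-0.273372262
CLNK	chr4	rs6448453	11026028	1.93E-09	Jansen	-39655	10984912	10986373	-0.7967249	1.351333931	-0.554603351
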