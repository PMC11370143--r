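gene_id	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12
g01	79	271	125	174	144	195	344	177	240	215	157	200
g02	152	565	386	229	406	355	265	517	239	222	192	320
g03	6	7	13	5	22	14	7	18	21	34	8	3
g04	70	67	131	50	61	101	70	59	33	75	29	55
g05	191	155	156	132	136	216	108	200	141	171	58	135
g06	7	25	24	14	31	33	24	25	14	8	9	17
g07	1016	1219	1820	410	1539	335	1352	2497	1547	1823	782	1210
g08	427	820	226	348	380	898	291	587	369	308	452	407
g09	79	73	48	52	104	66	32	73	93	73	39	49
g10	310	698	195	352	245	252	164	459	223	201	187	241
g11	441	272	428	344	87	447	189	442	320	126	137	123
g12	25	148	96	56	82	136	82	117	115	110	43	64
g13	17	23	21	25	20	40	8	24	17	23	15	6
g14	56	143	110	78	129	71	99	86	72	65	13	95
g15	198	53	175	64	137	273	209	124	153	112	54	72
g16	15	19	20	20	14	16	9	22	22	34	5	19
g17	458	1019	271	593	515	633	759	963	678	949	278	489
g18	134	135	245	110	44	219	165	72	94	197	119	96
g19	96	275	72	129	119	208	137	116	226	81	57	88
g20	82	232	157	95	51	204	152	204	225	204	134	70
g21	56	91	101	37	57	105	34	49	37	23	39	68
g22	33	40	36	44	11	31	13	27	18	41	22	27
g23	426	468	351	388	346	548	398	363	537	231	207	240
g24	51	94	85	64	61	45	20	35	86	34	60	47
g25	23	29	28	17	10	56	21	48	34	33	23	16
g26	6	24	9	15	12	13	4	10	16	10	5	9
g27	1813	2433	1420	1308	1574	1407	1539	1286	1081	1905	768	2054
g28	532	388	422	408	954	725	570	488	362	497	275	477
g29	52	25	86	42	81	98	50	91	53	42	27	66
g30	51	69	86	34	20	38	57	29	75	25	21	48
g31	340	596	428	279	596	515	318	538	303	292	202	549
g32	165	276	278	169	128	281	88	245	148	70	98	150
g33	366	723	774	614	626	1182	470	465	468	389	270	352
g34	4	6	10	6	8	11	4	9	2	9	2	4
g35	219	166	336	94	261	615	273	242	364	129	67	203
g36	152	211	362	152	178	198	142	364	517	222	102	191
g37	178	206	306	119	294	399	193	614	450	136	92	255
g38	40	74	85	41	46	83	60	41	40	31	18	15
g39	261	532	376	379	352	488	368	634	325	139	120	195
g40	13	41	20	27	33	45	16	15	11	16	11	11
g41	5078	9700	12844	5335	13851	19412	6529	4076	9209	7192	8650	6421
g42	1007	804	1160	497	896	1668	808	1074	765	628	229	440
g43	268	594	423	490	311	521	116	162	251	176	229	203
g44	1	8	5	5	7	4	3	5	1	1	3	4
g45	136	260	125	155	105	180	76	162	170	92	27	77
g46	194	540	340	194	161	469	424	534	318	118	150	176
g47	730	582	780	987	941	1497	710	507	576	518	324	252
g48	20	34	52	25	21	33	35	29	17	16	13	31
g49	62	277	69	135	85	91	122	121	141	59	58	109
g50	1753	2775	2560	2193	1297	4227	1337	2742	3203	1508	1410	1161
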