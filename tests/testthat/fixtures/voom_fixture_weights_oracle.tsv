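gene_id	1	2	3	4	5	6	7	8	9	10	11	12
g01	2.659075407	2.685614555	2.697044952	2.665476850	2.665025523	3.053278111	2.901401816	3.051388560	3.173205296	2.923078886	2.724549242	2.802853731
g02	2.979684153	3.411297801	3.422689633	2.954683529	3.390795744	3.477883795	3.186390996	3.289970298	3.383717829	3.203364810	3.004490053	3.092618155
g03	2.013667705	2.274940625	2.283146250	2.003055127	2.260102621	2.488812716	2.297278816	2.373101650	2.446202403	2.308149371	2.197019935	2.243447560
g04	2.776540596	2.716257398	2.713528444	2.781458777	2.721218521	2.621255165	2.794795831	2.764202270	2.741301861	2.789828305	2.844196045	2.819799463
g05	2.642587780	2.729274865	2.740938139	2.648939631	2.708266997	3.109149813	2.596079045	2.591646655	2.626257255	2.593943989	2.666880224	2.642157810
g06	2.415009539	2.671288393	2.677146005	2.402136055	2.660699176	2.785356495	2.447032252	2.528895980	2.596004415	2.458796241	2.340489271	2.389257532
g07	3.429175438	3.513955231	3.516289755	3.427966715	3.509723612	3.653794892	3.671361732	3.751689462	3.831327881	3.682251522	3.571575484	3.617513712
g08	3.329755441	3.470430582	3.465059733	3.313695364	3.480221193	3.458259998	3.474664843	3.520625891	3.488354509	3.490028104	3.335974559	3.399300852
g09	2.805701209	2.732083783	2.730498832	2.811302957	2.733589152	2.663246768	2.768969751	2.741880970	2.736264614	2.764841215	2.812968962	2.791317290
g10	2.943167817	3.387095488	3.398358471	2.918549188	3.366774955	3.489484095	2.989979312	3.128816451	3.235338657	3.012631686	2.796501397	2.881486319
g11	2.886270091	3.348225664	3.359327248	2.863993442	3.328195990	3.503031309	2.800784712	2.939520632	3.075629123	2.820124603	2.648383200	2.712926732
g12	2.770466709	2.710815735	2.708093613	2.774922017	2.715764434	2.604833696	2.721707694	2.697304698	2.670101638	2.718130590	2.736658645	2.732830666
g13	2.520591571	2.742028870	2.748899124	2.507011249	2.729615836	2.821015477	2.404548638	2.484841475	2.558713765	2.416057735	2.300300240	2.348021323
g14	2.739810075	2.673538866	2.669148027	2.740800157	2.681530206	2.598198858	2.750034854	2.737812242	2.731707843	2.745941571	2.790015810	2.770599461
g15	2.703593160	2.594011033	2.597470570	2.707571550	2.588830232	2.839700008	2.658858282	2.603761174	2.585746157	2.653157253	2.700921169	2.685588141
g16	2.325227428	2.611193514	2.616886828	2.312948993	2.597919630	2.753941190	2.483226737	2.562567178	2.622156818	2.495208763	2.374721237	2.424385066
g17	3.460816804	3.426978697	3.427803906	3.443802063	3.426801167	3.487608817	3.429294506	3.454098807	3.476976154	3.430374651	3.459863584	3.435116491
g18	2.701419386	2.596593675	2.601006719	2.705393778	2.591115719	2.851733559	2.639220301	2.591014105	2.600217473	2.629625200	2.688701250	2.667690259
g19	2.693106625	2.610176191	2.614618115	2.697065733	2.602139295	2.898491144	2.667770469	2.620521740	2.588159568	2.662045551	2.706452401	2.691080141
g20	2.716727430	2.587978756	2.586352330	2.720729999	2.590933571	2.768573933	2.613184753	2.689783024	2.797194258	2.619004044	2.592605922	2.588333440
g21	2.799046242	2.729320133	2.727737187	2.804631382	2.732195712	2.655631115	2.832911874	2.827919015	2.796075542	2.836971159	2.795348673	2.812724414
g22	2.647369918	2.799275924	2.802333249	2.638918067	2.793738298	2.809483939	2.683450251	2.737824397	2.769199728	2.691157544	2.612783769	2.645325771
g23	3.244926285	3.504156436	3.500359731	3.229210392	3.511059644	3.435392928	3.282429459	3.384298343	3.479811106	3.298816813	3.132336166	3.209737031
g24	2.820581344	2.734982708	2.734308223	2.826220263	2.736207258	2.680291764	2.845489161	2.808000679	2.776949392	2.837560435	2.811215976	2.828715188
g25	2.530569537	2.749435582	2.752425007	2.517300890	2.737201699	2.824443123	2.752848709	2.779835111	2.805147202	2.756765076	2.681193002	2.714805198
g26	2.124062021	2.399206211	2.407976151	2.112717768	2.383392731	2.610845385	2.104788157	2.175123568	2.242770656	2.114869837	2.013471202	2.055272291
g27	3.541172146	3.832062456	3.841790034	3.535797649	3.814487881	4.048900741	3.637530651	3.713216436	3.791832646	3.648295106	3.538888572	3.584301036
g28	3.461550196	3.427030601	3.427855825	3.444530950	3.426528927	3.487754241	3.526682785	3.492557889	3.451646543	3.521678689	3.418632880	3.484554280
g29	2.842456304	2.740249382	2.739573273	2.837901219	2.741476881	2.702194462	2.790145063	2.760345353	2.740473737	2.785187866	2.836979344	2.815096638
g30	2.784796490	2.794500871	2.790701906	2.780356589	2.801411548	2.736239485	2.826189978	2.836311668	2.804350188	2.830237225	2.788737971	2.806062322
g31	3.297446725	3.485868195	3.480457946	3.279116529	3.494174471	3.449289584	3.369988399	3.472504352	3.523834020	3.384634163	3.231190682	3.296809153
g32	2.598471643	3.000456591	3.017834595	2.593333175	2.969238212	3.327806498	2.613669253	2.585743756	2.614568388	2.602930574	2.678397477	2.653541688
g33	3.497559746	3.468068754	3.470374489	3.503114761	3.462350322	3.525334821	3.482785507	3.517981984	3.484605318	3.494350832	3.343618568	3.407126722
g34	1.860608361	2.099624482	2.107304496	1.850719375	2.085776357	2.298274436	1.794746774	1.854015110	1.911156870	1.803243869	1.717755519	1.753004985
g35	2.670564543	3.162359202	3.175426985	2.654054390	3.135138979	3.447171832	2.748748612	2.881564052	3.020801897	2.767640023	2.620883232	2.672036655
g36	2.590145571	2.956186918	2.973244786	2.585972527	2.925542489	3.298713857	2.933651786	3.080094964	3.198258916	2.955771497	2.748432288	2.831588361
g37	2.648212360	3.132601513	3.147549448	2.631874627	3.105700746	3.424243427	3.014022277	3.149551554	3.250266736	3.035983458	2.816988739	2.902843369
g38	2.844378145	2.739832300	2.739156320	2.839819211	2.741059565	2.700521595	2.777532259	2.804821840	2.830418974	2.781492578	2.730001868	2.757836451
g39	3.187440398	3.523342226	3.519519523	3.168562707	3.521379710	3.427603396	3.083275633	3.209360843	3.304204119	3.102457375	2.884554075	2.978582943
g40	2.612152341	2.780595923	2.783627763	2.601737146	2.775104439	2.833108271	2.373276695	2.452261026	2.528282133	2.384598887	2.270711083	2.317664141
g41	4.730206563	4.859992777	4.859992777	4.715248679	4.859992777	4.859992777	4.704535152	4.796793630	4.859992777	4.717854960	4.582376873	4.638638084
g42	3.440042360	3.524753618	3.527097113	3.435474424	3.520505740	3.692203500	3.428840959	3.438165551	3.464218826	3.426171795	3.486126680	3.457308014
g43	3.249889840	3.502407140	3.498612804	3.234143910	3.509306040	3.436829016	2.734432626	2.864695362	3.001502399	2.751600222	2.615940077	2.659503355
g44	1.701702635	1.864009081	1.870816814	1.701702635	1.851733678	2.038091310	1.701702635	1.701702635	1.701702635	1.701702635	1.701702635	1.701702635
g45	2.659630330	2.684166154	2.695588842	2.666033443	2.663590988	3.051362312	2.715553861	2.691219738	2.660245777	2.711986864	2.735139413	2.729609110
g46	2.835682944	3.311417290	3.322366467	2.813892805	3.289559828	3.515765479	3.066508151	3.194633022	3.289739766	3.085559488	2.867028429	2.958906968
g47	3.428832634	3.512986575	3.515320294	3.427624062	3.508756413	3.650366801	3.513256644	3.474376219	3.436342570	3.508276346	3.459261411	3.508667154
g48	2.636338172	2.793441296	2.796490657	2.627930305	2.787918091	2.816815203	2.661008158	2.713841129	2.757670541	2.668634936	2.585173813	2.623281107
g49	2.734284420	2.637870269	2.629588032	2.735272006	2.645728513	2.642722406	2.694024676	2.661923667	2.614903302	2.690492987	2.726047147	2.711769941
g50	3.757660340	4.056723232	4.065182601	3.743816793	4.041427755	4.272179131	3.801456391	3.888889026	3.960938410	3.814057042	3.687775202	3.739229168
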