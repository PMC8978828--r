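sample_id	taxon_1	taxon_2	taxon_3	taxon_4	taxon_5	taxon_6	taxon_7	taxon_8	taxon_9	taxon_10	taxon_11	taxon_12	taxon_13	taxon_14	taxon_15
sample_1	3440376	999554	545264	935939	792995	706417	893292	472769	858957	846697	3263	3548	1062	4615	2261
sample_2	4637232	1394526	776099	1268560	1077776	971392	1171398	591560	1107349	1150197	1845	2895	3316	1411	1978
sample_3	997802	307168	162220	271630	232607	223170	256055	136438	228001	252924	134	737	906	37	367
sample_4	8127325	2366180	1312181	2101559	1854539	1723879	2166863	1083598	1921674	1934439	2798	3465	8334	1497	2339
sample_5	2383791	686864	411910	657100	555457	539646	624129	302181	604870	589818	2114	1705	5329	774	412
sample_6	5960616	1719444	1014119	1675713	1452296	1262102	1537986	822723	1387223	1503355	3793	4588	3400	3203	4122
sample_7	2052313	622176	323877	548350	481719	435865	511736	269179	495336	507636	441	1795	509	573	372
sample_8	2962207	921137	481528	826377	723827	625741	778647	398008	731086	746610	1642	1670	1828	994	1509
sample_9	1515135	464686	229026	431566	348043	327420	388967	189469	353105	383810	1632	630	1587	343	739
sample_10	13506660	3974801	2125281	3929825	3229565	2644049	3551717	1705658	3268368	3405718	2599	4203	11762	1059	14295
sample_11	386125	113403	61643	101955	93325	81641	103460	50919	91271	96315	29	188	315	80	448
sample_12	302350	88414	45722	79182	69477	62682	76314	39833	71204	72858	91	311	397	45	197
sample_13	3383848	282186	118855	181822	213017	286722	118485	296327	281612	104605	990	1325	270	178	1074
sample_14	641346	55527	22239	35994	39930	52774	22793	55444	52283	22449	50	77	162	117	166
sample_15	6745061	591271	236490	375094	407770	549382	256635	598528	585762	226317	847	1158	1886	528	2846
sample_16	4607977	376090	161917	253858	272166	359523	170134	399385	391971	152261	765	938	483	676	382
sample_17	3593287	319951	129524	214212	218312	286163	129690	320799	324354	108885	273	478	722	455	1166
sample_18	8960623	768784	344742	548657	548018	699892	309840	759204	738841	285341	1845	527	1346	1587	3592
sample_19	6354806	534521	240835	347934	394707	508517	234400	562605	564477	210774	843	252	4912	2731	2517
sample_20	755549	65969	27095	43545	46286	59187	28605	65299	61750	25940	178	60	273	63	137
sample_21	13956363	1189552	510695	789506	836628	1079626	504296	1205433	1147001	491873	1255	1233	1663	566	3265
sample_22	68415	6076	2624	3859	4114	5637	2391	5710	5747	2365	7	6	25	2	38
sample_23	7653470	649282	274123	419773	454999	628919	277898	636851	662469	262152	401	2893	1889	273	5374
sample_24	14516572	1270808	548862	862570	881605	1104773	497039	1187248	1248917	511347	854	5109	2592	3225	2236
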