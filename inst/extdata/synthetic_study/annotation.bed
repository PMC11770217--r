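chr1	10606	12168
chr1	22248	23769
chr1	26974	27605
chr1	35552	39050
chr1	44352	45228
chr1	59164	59559
chr1	70275	71102
chr1	77984	78844
chr1	80148	80792
chr1	171895	172569
chr1	183625	184285
chr1	231064	232776
chr1	239900	240757
chr1	246262	247140
chr1	260394	261107
chr1	273088	274399
chr1	280231	281860
chr1	370497	373310
chr1	374258	375969
chr1	399723	400233
chr1	414900	415603
chr1	431790	433854
chr1	445290	445789
chr1	456435	457281
chr1	459878	460607
chr1	497888	499350
chr1	516583	517437
chr1	532880	533468
chr1	578138	578750
chr1	586578	587967
chr1	602494	603630
chr1	607210	608329
chr1	609620	612399
chr1	612674	613368
chr1	613854	614524
chr1	616391	616966
chr1	626050	626886
chr1	643060	644592
chr1	670519	670909
chr1	674890	675797
chr1	685803	686971
chr1	694193	694904
chr1	711370	712371
chr1	718262	719224
chr1	731322	732625
chr1	768567	769590
chr1	785612	786274
chr1	796916	798113
chr1	800454	801146
chr1	840370	841461
chr1	877811	878721
chr1	887537	888614
chr1	892018	893145
chr1	895034	896559
chr1	984888	985906
chr1	1011771	1013671
chr1	1032780	1033809
chr1	1074558	1075432
chr1	1081823	1082841
chr1	1088460	1090091
chr1	1098121	1100837
chr1	1111538	1112660
chr1	1128221	1128945
chr1	1185404	1186643
chr1	1187166	1188256
chr1	1198844	1199769
chr1	1208230	1209211
chr1	1222237	1223901
chr1	1288964	1289719
chr1	1329175	1330193
chr1	1349892	1351157
chr1	1365755	1368468
chr1	1368891	1369501
chr1	1390138	1391136
chr1	1397307	1397888
chr1	1424077	1424801
chr1	1439821	1440740
chr1	1477120	1477660
chr1	1480343	1480831
chr1	1481346	1481629
chr1	1495477	1497625
chr1	1507625	1508102
chr1	1534913	1536195
chr1	1575048	1576369
chr1	1664603	1665655
chr1	1693658	1694949
chr1	1698070	1699268
chr1	1737517	1738641
chr1	1745688	1746290
chr1	1747252	1748777
chr1	1751475	1753648
chr1	1838527	1840001
chr1	1845738	1847205
chr1	1919531	1920469
chr1	1937700	1938675
chr1	1972487	1972875
chr2	51247	51977
chr2	57403	58292
chr2	79653	82174
chr2	122908	123945
chr2	126250	127155
chr2	159031	159763
chr2	170447	171043
chr2	189482	190376
chr2	204967	206496
chr2	216034	217743
chr2	218017	219034
chr2	240826	241365
chr2	241943	242399
chr2	248111	249669
chr2	257637	259591
chr2	290755	292493
chr2	302017	303877
chr2	308786	309267
chr2	309669	311291
chr2	314870	315568
chr2	342251	343157
chr2	348769	349354
chr2	379917	380576
chr2	382758	383655
chr2	469317	470236
chr2	491875	493021
chr2	517794	518985
chr2	576917	578068
chr2	584326	584972
chr2	591790	592541
chr2	654082	655743
chr2	671688	672905
chr2	684600	686199
chr2	712370	714219
chr2	730415	731432
chr2	756661	757794
chr2	801761	802177
chr2	811958	812340
chr2	830667	832631
chr2	837036	837689
chr2	850967	851672
chr2	852707	853242
chr2	871991	872433
chr2	890492	890897
chr2	946652	948755
chr2	999070	1000855
chr2	1039355	1040121
chr2	1056902	1057619
chr2	1078190	1079366
chr2	1111420	1112889
chr2	1138078	1138783
chr2	1145639	1146867
chr2	1183321	1184690
chr2	1189520	1190587
chr2	1197441	1198297
chr2	1214816	1216263
chr2	1220127	1221056
chr2	1240304	1241098
chr2	1250539	1253617
chr2	1255646	1257528
chr2	1264999	1265808
chr2	1267822	1268419
chr2	1316726	1317843
chr2	1319153	1319390
chr2	1360413	1360914
chr2	1370966	1371431
chr2	1384015	1384431
chr2	1411993	1413601
chr2	1432189	1433226
chr2	1439196	1441160
chr2	1455086	1456153
chr2	1485405	1486469
chr2	1512069	1512885
chr2	1518602	1520567
chr2	1565530	1566766
chr2	1647476	1648440
chr2	1680878	1682170
chr2	1701382	1703146
chr2	1724705	1725756
chr2	1730454	1730886
chr2	1745536	1746446
chr2	1778030	1779593
chr2	1782030	1782812
chr2	1800822	1802355
chr2	1850957	1851686
chr2	1864938	1865984
chr2	1869781	1871610
chr2	1874343	1875175
chr2	1912893	1914283
chr2	1958309	1959055
chr2	1982730	1984293
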