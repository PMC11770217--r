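chrom	pos	id	pvalue
chr2	1944606	T002_rs0001	3.7584556685711724e-8
chr2	1531589	T002_rs0002	3.088152795030968e-8
chr1	1066680	T002_rs0003	2.957496506446786e-8
chr1	43258	T002_rs0004	1.883137942470354e-8
chr1	777417	T002_rs0005	9.991127195474924e-9
chr1	288053	T002_rs0006	2.5771941131920086e-8
chr2	886488	T002_rs0007	4.3646405027380214e-8
chr2	1530863	T002_rs0008	9.398116403026272e-9
chr2	1422879	T002_rs0009	4.5785450489327076e-8
chr2	951512	T002_rs0010	4.727715264202212e-8
chr2	519644	T002_rs0011	3.6226300377271134e-8
chr2	191825	T002_rs0012	4.480376498328755e-9
chr1	702431	T002_rs0013	4.078452962420648e-8
chr1	221119	T002_rs0014	3.917026281960914e-8
chr1	1955754	T002_rs0015	2.5780741465295664e-8
chr1	404741	T002_rs0016	5.306554770392831e-10
chr2	1082329	T002_rs0017	2.3237745949269736e-9
chr1	1193027	T002_rs0018	3.7678045970145844e-8
chr1	1276103	T002_rs0019	3.642945499724103e-8
chr2	836064	T002_rs0020	1.1917652577199274e-8
chr2	1524471	T002_rs0021	2.563927285661455e-8
chr2	1610911	T002_rs0022	4.0767623128135684e-8
chr2	1971982	T002_rs0023	1.60815519302967e-9
chr2	170341	T002_rs0024	3.315773796481732e-8
chr2	132512	T002_rs0025	4.478629933726834e-8
chr2	1089982	T002_rs0026	1.6699226426864043e-8
chr2	1209420	T002_rs0027	3.684129406391643e-8
chr1	63286	T002_rs0028	6.358258384754182e-9
chr1	74708	T002_rs0029	3.569143669931474e-8
chr1	1858410	T002_rs0030	1.2960894440434639e-8
chr1	927208	T002_rs0031	8.402055701630422e-9
chr2	1566792	T002_rs0032	5.445585847268579e-9
chr2	1657149	T002_rs0033	1.1669846270177515e-9
chr1	245954	T002_rs0034	3.159891410070238e-9
chr2	199453	T002_rs0035	1.7775636598724173e-8
chr2	1540579	T002_rs0036	6.166087726527127e-9
chr2	578262	T002_rs0037	4.9072498379595576e-8
chr1	1265096	T002_rs0038	4.2229212801644576e-8
chr1	637347	T002_rs0039	2.500281977336318e-8
chr1	1837060	T002_rs0040	1.2521870960751314e-8
chr2	1539033	T002_rs0041	5.711625241328031e-9
chr1	321008	T002_rs0042	4.2151444009344554e-8
chr1	162171	T002_rs0043	4.3858004781399854e-8
chr1	622271	T002_rs0044	3.717026161918812e-8
chr1	1321596	T002_rs0045	1.6793077918686205e-8
chr2	323417	T002_rs0046	3.3506332657666174e-8
chr2	887185	T002_rs0047	2.8750433316258712e-9
chr2	1550181	T002_rs0048	1.8325359114760532e-8
chr2	864847	T002_rs0049	2.3740649143275105e-8
chr2	682030	T002_rs0050	2.4573170519830892e-8
chr1	709244	T002_rs0051	6.0332942956122565e-9
chr1	1498735	T002_rs0052	2.0484935137320777e-8
chr1	1191370	T002_rs0053	2.341914716491918e-8
chr1	1766841	T002_rs0054	3.4330347143079156e-8
chr2	1211835	T002_rs0055	3.515254484075005e-8
chr2	510069	T002_rs0056	3.782976768815517e-8
chr1	1890511	T002_rs0057	4.550655690057738e-8
chr2	589106	T002_rs0058	1.6917884405452526e-8
chr1	1468796	T002_rs0059	2.524282688217028e-8
chr1	1262209	T002_rs0060	3.5396340261192295e-8
chr2	493120	T002_rs0061	1.8456414604453835e-8
chr2	162891	T002_rs0062	2.467890180630493e-8
chr2	1313574	T002_rs0063	4.205945954911248e-8
chr1	25212	T002_rs0064	3.87497664096381e-8
chr2	1462242	T002_rs0065	2.6696907300608232e-8
chr1	445116	T002_rs0066	4.24545822687007e-8
chr1	977311	T002_rs0067	3.7268386254538784e-9
chr2	1217064	T002_rs0068	1.8795915633165274e-9
chr1	441128	T002_rs0069	2.8310483077676033e-8
chr2	341696	T002_rs0070	3.737004099080572e-9
chr1	1019097	T002_rs0071	3.6430002924976865e-9
chr2	865445	T002_rs0072	4.721751424885821e-9
chr2	564989	T002_rs0073	3.429655035562627e-8
chr1	813145	T002_rs0074	1.1011986413935198e-8
chr2	1211164	T002_rs0075	4.1407023474067915e-8
chr2	821654	T002_rs0076	1.2052167511821025e-8
chr1	262493	T002_rs0077	1.981539081084635e-8
chr1	1944623	T002_rs0078	4.552645579934586e-9
chr2	729102	T002_rs0079	8.82110719352588e-9
chr1	781077	T002_rs0080	3.635573468797537e-8
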