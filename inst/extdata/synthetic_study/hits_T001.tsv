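chrom	pos	id	pvalue
chr1	776271	T001_rs0001	2.7321647874679416e-8
chr1	1268846	T001_rs0002	2.9167137484777486e-8
chr2	760905	T001_rs0003	1.583194716882217e-8
chr2	1038444	T001_rs0004	4.8795894052363466e-8
chr2	214784	T001_rs0005	2.324309708700236e-8
chr1	1250435	T001_rs0006	4.236480837480258e-8
chr2	1733647	T001_rs0007	3.4394051976860264e-8
chr1	1214182	T001_rs0008	2.71204465483278e-8
chr2	1798290	T001_rs0009	2.2144702286391986e-8
chr1	677261	T001_rs0010	2.9849709088780914e-8
chr1	901588	T001_rs0011	9.992450787928653e-9
chr1	1309144	T001_rs0012	3.816454659170471e-8
chr2	600320	T001_rs0013	5.1991385853991375e-9
chr2	972431	T001_rs0014	2.3550962028210516e-8
chr1	1516267	T001_rs0015	2.2037894994618838e-8
chr1	1566940	T001_rs0016	2.900729812575178e-8
chr2	1075309	T001_rs0017	2.3270422348091146e-8
chr2	1940620	T001_rs0018	3.42908849543184e-8
chr2	1215878	T001_rs0019	2.9090340980498583e-9
chr2	586957	T001_rs0020	3.6495391288546376e-9
chr2	683142	T001_rs0021	8.99599503903929e-9
chr1	10630	T001_rs0022	5.4936751585118474e-9
chr2	1679442	T001_rs0023	4.004969203193695e-8
chr2	990305	T001_rs0024	2.3893293969757855e-8
chr1	1388286	T001_rs0025	3.1263352860213256e-8
chr2	216768	T001_rs0026	3.4691245932658666e-8
chr2	554249	T001_rs0027	2.3096715291212313e-8
chr1	1839843	T001_rs0028	1.0317360279376617e-8
chr2	510265	T001_rs0029	8.730255862448829e-9
chr1	1397269	T001_rs0030	2.47578482595738e-10
chr2	1213471	T001_rs0031	3.8992527884795796e-8
chr2	1906947	T001_rs0032	3.472734618401434e-8
chr2	1202681	T001_rs0033	1.2952040673495036e-8
chr1	477820	T001_rs0034	1.1806910386549541e-8
chr1	1920490	T001_rs0035	2.0068590468709358e-8
chr2	260603	T001_rs0036	1.4752879812178432e-8
chr1	434666	T001_rs0037	1.4159201234932988e-9
chr1	790929	T001_rs0038	2.6318199057573685e-8
chr2	1120969	T001_rs0039	3.381719642087002e-8
chr2	1684803	T001_rs0040	2.1227616951408797e-8
chr2	169538	T001_rs0041	3.304455247497698e-8
chr1	452918	T001_rs0042	1.5582648510372034e-8
chr2	257582	T001_rs0043	4.01171008361394e-8
chr1	1984939	T001_rs0044	2.586754085093038e-9
chr1	559972	T001_rs0045	2.0660112455383875e-8
chr2	1777800	T001_rs0046	4.9456941871734104e-8
chr1	887547	T001_rs0047	4.834278704513702e-8
chr2	1400739	T001_rs0048	2.3518021877411753e-8
chr1	1086693	T001_rs0049	1.7166207592864753e-8
chr1	1706236	T001_rs0050	4.689114164892584e-8
chr1	1074881	T001_rs0051	5.1371248133271e-9
chr1	209279	T001_rs0052	3.4902463386407585e-8
chr2	1014695	T001_rs0053	4.76943099897413e-8
chr1	1727917	T001_rs0054	4.4533910612318197e-8
chr1	1497990	T001_rs0055	8.38250744549767e-9
chr2	495442	T001_rs0056	4.447907453947025e-8
chr2	1142717	T001_rs0057	1.2281249785044695e-8
chr2	1297689	T001_rs0058	2.8590433067776727e-8
chr2	1259355	T001_rs0059	3.1251264593172585e-8
chr2	166704	T001_rs0060	1.0704814060190691e-8
chr2	258435	T001_rs0061	1.951714965032344e-8
chr1	771067	T001_rs0062	7.380595554355531e-10
chr1	262473	T001_rs0063	4.9639029825972854e-8
chr1	608031	T001_rs0064	2.719557486110879e-8
chr1	961505	T001_rs0065	3.09730247565119e-8
chr2	1648672	T001_rs0066	3.766364451871742e-8
chr1	1008440	T001_rs0067	1.4974194218866062e-8
chr1	1035330	T001_rs0068	1.973090192715847e-8
chr1	610134	T001_rs0069	2.4704763751123096e-9
chr2	1780393	T001_rs0070	5.8631961812281516e-9
chr1	643492	T001_rs0071	8.348662493047304e-10
chr1	995207	T001_rs0072	2.692740517911571e-8
chr2	1079514	T001_rs0073	3.134262247210834e-8
chr2	1146273	T001_rs0074	1.805571302497713e-8
chr1	11128	T001_rs0075	4.200703888290189e-8
chr2	1924413	T001_rs0076	2.8730856322699924e-8
chr2	891605	T001_rs0077	1.883915003858623e-8
chr2	1779097	T001_rs0078	9.874061643977184e-10
chr2	259053	T001_rs0079	4.920359624361852e-8
chr2	1019508	T001_rs0080	6.11696047703363e-9
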