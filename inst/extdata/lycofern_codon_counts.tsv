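amino_acid	codon	ac	cr	dc	sm
Ala	GCA	328432	989237	1115071	214300
Ala	GCC	173863	376265	438127	244188
Ala	GCG	91978	216035	220899	248354
Ala	GCU	301610	864565	1051993	277044
Cys	UGC	119373	318043	311419	145304
Cys	UGU	114153	396826	364193	73974
Asp	GAC	200175	514792	569822	311951
Asp	GAU	378798	1281555	1331887	304291
Glu	GAA	328776	1157275	1341654	272737
Glu	GAG	393172	1061377	1123251	483614
Phe	UUC	173387	536715	507514	268206
Phe	UUU	263340	782464	910388	206909
Gly	GGA	213205	714541	837986	250272
Gly	GGC	182091	422746	489520	242831
Gly	GGG	155260	404290	427736	157826
Gly	GGU	200691	629334	662767	145882
His	CAC	108927	272492	306282	165967
His	CAU	197221	645662	639124	113122
Ile	AUA	132939	495964	476885	89876
Ile	AUC	155759	472970	492669	282736
Ile	AUU	233749	772433	845577	174532
Lys	AAA	264644	906517	1046153	208904
Lys	AAG	356189	994699	1049801	421403
Leu	CUA	114756	342395	398912	92206
Leu	CUC	168150	414007	386053	331224
Leu	CUG	182510	514216	600222	277257
Leu	CUU	279707	857324	932495	200373
Leu	UUA	123649	451252	468975	60664
Leu	UUG	269356	759794	874982	215282
Met	AUG	282681	866305	860493	276469
Asn	AAC	163371	483812	520991	238044
Asn	AAU	259882	906830	953288	160282
Pro	CCA	184259	582251	663628	178328
Pro	CCC	109951	234875	252967	115033
Pro	CCG	61060	153096	151889	144537
Pro	CCU	202036	588760	695197	131240
Gln	CAA	247609	716536	854813	184836
Gln	CAG	224626	678388	783813	264729
Arg	AGA	163721	556336	601738	137503
Arg	AGG	153253	456708	443328	160121
Arg	CGA	82637	238749	295095	107147
Arg	CGC	79522	167607	190657	116118
Arg	CGG	65558	173829	182712	111949
Arg	CGU	72345	244908	286909	68380
Ser	AGC	179597	440360	505404	236996
Ser	AGU	161155	537111	588387	104037
Ser	UCA	205493	738956	786199	102542
Ser	UCC	136411	378592	385704	178370
Ser	UCG	78268	211624	222177	185204
Ser	UCU	236121	772144	837411	144767
Thr	ACA	205060	670959	703525	127562
Thr	ACC	115165	265042	305155	131863
Thr	ACG	66861	184439	189383	154925
Thr	ACU	161738	532033	615793	144121
Val	GUA	128256	433311	448957	82007
Val	GUC	137417	379589	378766	211259
Val	GUG	250181	619010	715051	312706
Val	GUU	225220	729989	848969	206157
Trp	UGG	148751	416101	457356	168797
Tyr	UAC	119310	326033	350895	192562
Tyr	UAU	168731	591712	592105	116394
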