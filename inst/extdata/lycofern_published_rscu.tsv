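amino_acid	codon	ac	cr	dc	sm
Ala	GCA	1.466	1.618	1.578	0.871
Ala	GCC	0.776	0.615	0.62	0.993
Ala	GCG	0.411	0.353	0.313	1.01
Ala	GCU	1.347	1.414	1.489	1.126
Cys	UGC	1.022	0.89	0.922	1.325
Cys	UGU	0.978	1.11	1.078	0.675
Asp	GAC	0.691	0.573	0.599	1.012
Asp	GAU	1.309	1.427	1.401	0.988
Glu	GAA	0.911	1.043	1.089	0.721
Glu	GAG	1.089	0.957	0.911	1.279
Phe	UUC	0.794	0.814	0.716	1.129
Phe	UUU	1.206	1.186	1.284	0.871
Gly	GGA	1.135	1.317	1.386	1.256
Gly	GGC	0.97	0.779	0.81	1.219
Gly	GGG	0.827	0.745	0.708	0.792
Gly	GGU	1.069	1.16	1.096	0.732
His	CAC	0.712	0.594	0.648	1.189
His	CAU	1.288	1.406	1.352	0.811
Ile	AUA	0.763	0.854	0.788	0.493
Ile	AUC	0.894	0.815	0.814	1.55
Ile	AUU	1.342	1.331	1.398	0.957
Lys	AAA	0.853	0.954	0.998	0.663
Lys	AAG	1.147	1.046	1.002	1.337
Leu	CUA	0.616	0.644	0.688	0.409
Leu	CUC	0.903	0.778	0.666	1.47
Leu	CUG	0.98	0.967	1.036	1.231
Leu	CUU	1.502	1.612	1.609	0.889
Leu	UUA	0.629	0.745	0.698	0.44
Leu	UUG	1.371	1.255	1.302	1.56
Met	AUG	1	1	1	1
Asn	AAC	0.772	0.696	0.707	1.195
Asn	AAU	1.228	1.304	1.293	0.805
Pro	CCA	1.322	1.494	1.505	1.253
Pro	CCC	0.789	0.603	0.574	0.808
Pro	CCG	0.438	0.393	0.344	1.016
Pro	CCU	1.45	1.511	1.577	0.922
Gln	CAA	1.049	1.027	1.043	0.822
Gln	CAG	0.951	0.973	0.957	1.178
Arg	AGA	1.033	1.098	1.152	0.924
Arg	AGG	0.967	0.902	0.848	1.076
Arg	CGA	1.102	1.157	1.236	1.062
Arg	CGC	1.06	0.813	0.798	1.151
Arg	CGG	0.874	0.843	0.765	1.11
Arg	CGU	0.964	1.187	1.201	0.678
Ser	AGC	1.054	0.901	0.924	1.39
Ser	AGU	0.946	1.099	1.076	0.61
Ser	UCA	1.252	1.407	1.409	0.671
Ser	UCC	0.831	0.721	0.691	1.168
Ser	UCG	0.477	0.403	0.398	1.213
Ser	UCU	1.439	1.47	1.501	0.948
Thr	ACA	1.495	1.624	1.551	0.914
Thr	ACC	0.839	0.642	0.673	0.944
Thr	ACG	0.487	0.446	0.418	1.11
Thr	ACU	1.179	1.288	1.358	1.032
Val	GUA	0.692	0.802	0.751	0.404
Val	GUC	0.742	0.702	0.633	1.041
Val	GUG	1.35	1.145	1.196	1.54
Val	GUU	1.216	1.351	1.42	1.015
Trp	UGG	1	1	1	1
Tyr	UAC	0.828	0.711	0.744	1.247
Tyr	UAU	1.172	1.289	1.256	0.753
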