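gene	mirnas	logFC_GSE29746	p_GSE29746	logFC_GSE7669	p_GSE7669	logFC_GSE49604	p_GSE49604
ATXN7	miR-19b; miR-23b	1.479	0.026	0.183	0.697	0.189	0.226
CADM1	miR-124; miR-34a*	1.597	0.132	0.879	0.036	0.429	0.236
CBLN1	miR-23b	1.269	0.065	0.357	0.423	0.099	0.432
CDH11	miR-34a*	0.088	0.693	1.053	0.001	0.008	0.973
CHST1	miR-19b; miR-30a	1.216	0.213	0.108	0.608	0.077	0.521
EDNRA	miR-30a	0.584	0.170	1.468	0.036	0.249	0.272
GATA6	miR-124	0.258	0.642	1.086	0.098	0.008	0.952
GPR116	miR-34a*	1.743	0.001	0.036	0.909	0.006	0.962
GRIA2	miR-124; miR-30a	1.671	0.003	0.043	0.927	0.099	0.450
HDAC2	miR-34a*	1.079	0.001	0.347	0.177	0.145	0.207
HPRT1	miR-19b	1.173	0.020	0.090	0.641	0.172	0.251
INHBB	miR-19b	1.053	0.065	2.124	0.011	0.005	0.971
JUN	miR-34a*	1.246	0.002	0.692	0.169	0.235	0.170
KCNA4	miR-19b; miR-30a	1.242	0.390	0.426	0.507	0.028	0.847
KIAA0040	miR-22	1.104	0.112	0.546	0.247	0.175	0.135
KIAA0408	miR-30a	1.219	0.017	1.250	0.111	0.033	0.822
LIF	miR-124	1.201	0.031	0.366	0.708	0.046	0.752
MICAL2	miR-19b	1.975	0.000	1.216	0.001	0.005	0.987
NAPG	miR-30a	1.052	0.048	0.036	0.858	0.084	0.557
NID1	miR-124	0.448	0.540	1.038	0.005	0.044	0.726
NR5A2	miR-30a	2.038	0.009	0.135	0.845	0.144	0.227
NRP1	miR-124	1.061	0.051	0.863	0.040	0.164	0.232
NRP2	miR-30a	1.056	0.179	1.833	0.046	0.213	0.073
PCDH1	miR-124	1.885	0.001	0.906	0.040	0.054	0.632
PDE12	miR-124	0.456	0.385	1.047	0.044	0.103	0.383
PIK3CD	miR-30a	0.982	0.012	1.068	0.028	0.171	0.322
PPFIA2	miR-19b; miR-30a	1.785	0.000	0.191	0.428	0.166	0.204
PPIF	miR-124; miR-23b	1.339	0.013	0.145	0.633	0.110	0.322
ROR2	miR-124	2.545	0.000	0.679	0.064	0.351	0.270
RRM2	miR-34a*	0.757	0.227	1.214	0.005	0.591	0.019
SAMD4A	miR-30a	1.053	0.004	0.374	0.224	0.186	0.312
SCN8A	miR-30a	1.011	0.123	0.045	0.865	0.233	0.087
SLC6A1	miR-22	2.095	0.037	0.925	0.129	0.054	0.632
SMOX	miR-124	0.468	0.441	1.323	0.069	0.284	0.034
SV2A	miR-19b; miR-22	1.315	0.070	0.320	0.153	0.336	0.036
TJP2	miR-124	1.395	0.001	1.077	0.034	0.404	0.005
TNFAIP6	miR-23b	1.015	0.101	0.763	0.450	0.167	0.661
TXK	miR-19b	1.181	0.021	0.706	0.242	0.241	0.086
WHSC1	miR-23b	1.414	0.003	0.178	0.385	0.262	0.191
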