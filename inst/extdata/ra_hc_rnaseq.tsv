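gene	mirnas	fpkm_hc	fpkm_ra	logFC	p
LASP1	miR-203a	1354.390	192.980	-2.811	0.037
ALCAM	miR-323	124.208	20.470	-2.601	0.002
SFRP1	miR-203a	97.100	4.420	-4.457	0.000
LRRC59	miR-155	91.001	24.123	-1.916	0.015
GYS1	miR-203a	76.312	19.463	-1.971	0.012
B4GALT1	miR-124	60.335	237.812	1.979	0.030
KCTD9	miR-203a	34.506	10.346	-1.738	0.019
CCDC50	miR-203a	33.295	9.508	-1.808	0.036
ATP6V1B2	miR-19b; miR-23b	32.409	120.477	1.894	0.016
ID4	miR-203a	28.005	3.079	-3.185	0.001
STOM	miR-124	27.766	152.788	2.460	0.003
FAP	miR-30a	14.053	105.083	2.903	0.001
ABI3BP	miR-30a	9.932	130.092	3.711	0.009
SMOC2	miR-19b	3.227	27.262	3.079	0.009
ROR2	miR-124	0.224	9.619	5.427	0.002
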