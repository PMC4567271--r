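gene	mirnas	logFC_GSE21959	p_GSE21959	logFC_GSE29746	p_GSE29746
ABI3BP	miR-30a	1.394	0.012	1.304	0.054
CCDC67	miR-22; miR-34a*	1.102	0.052	1.398	0.016
CHD7	miR-30a	2.167	0.001	1.006	0.240
DMRT2	miR-203a	-4.259	0.000	-1.413	0.290
DSG2	miR-124	1.324	0.240	1.493	0.128
ESPN	miR-30a	1.676	0.049	1.118	0.207
MAPK10	miR-221; miR-222	-2.308	0.004	-1.488	0.116
PAWR	miR-30a	1.294	0.024	1.305	0.176
PTPRB	miR-23b	1.211	0.058	1.965	0.035
ROR2	miR-124	1.175	0.060	1.555	0.013
SMOC2	miR-19b	1.223	0.015	1.495	0.212
UCP3	miR-19b; miR-30a	1.266	0.154	1.041	0.243
XKR6	miR-34a*	1.378	0.057	1.092	0.277
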