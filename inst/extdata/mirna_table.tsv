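mirna_id	previous_ids	direction	n_source_a	n_source_b	n_common	p_printed
miR-19b-3p	miR-19b	down	1171	786	577	0.00
miR-22-3p	miR-22	down	508	430	231	0.01
miR-23b-3p	miR-23b	down	1127	866	527	0.00
miR-30a-5p	miR-30a	down	1357	842	629	0.00
miR-34a-3p	miR-34a*	down	NA	233	233	NA
miR-124-3p	miR-124a; miR-124	down	1654	901	692	0.00
miR-146a-5p	miR-146; miR-146a	up	224	224	60	1.00
miR-155-5p	miR-155	up	440	311	143	0.00
miR-203a-3p	miR-203a	up	868	711	313	0.00
miR-214-3p	miR-214	up	678	790	251	0.04
miR-221-3p	miR-221	up	446	316	161	0.00
miR-222-3p	miR-222	up	446	320	159	0.00
miR-223-3p	miR-223	up	311	242	99	0.03
miR-323a-3p	miR-323; miR-323-3p	up	528	389	141	0.00
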