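subset	n	d	c	dc
correlation_cutoff30	741436	14211	62365	1988
correlation_cutoff125	538283	10508	46022	1498
conservation_loose	741436	14211	459030	10273
conservation_intermediate	741436	14211	144591	4892
conservation_strict	741436	14211	53443	2402
contact	70589	2747	59079	2522
correlation_conservation_filtered_a	287029	3961	16271	388
correlation_conservation_filtered_b	599322	9328	49254	1463
correlation_conservation_filtered_c	688790	11799	61802	1955
correlation_non_contact	70589	2747	4960	252
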