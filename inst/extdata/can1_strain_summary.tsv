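strain	rate_1e7	ci_low_1e7	ci_high_1e7	n_isolates	base_substitutions	single_base_indels	others	total_mutations	pool_imbalanced	mmr_deficient
wt	4.2	1.6	4.4	93	65	11	17	93	FALSE	FALSE
rnr1_OR1	57	43	103	173	72	101	0	173	TRUE	FALSE
rnr1_OR2	60	40	108	170	80	104	0	184	TRUE	FALSE
msh2	66	53.4	90	164	62	106	1	169	FALSE	TRUE
rnr1_msh2	2236	1883	3272	259	131	130	3	264	TRUE	TRUE
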