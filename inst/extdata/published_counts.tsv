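quantity	k	n
kb_all_genes	4542	18904
kb_tnf_modulated	77	193
hse_all_genes	1188	18904
hs_induced_hsf1_all_genes	2104	18904
hsf1_bound_tnf_modulated	48	193
hsf1_bound_hs_modulated	360	1527
tnf_genes_coaffected_by_hs	120	193
mode_coactivated	23	193
mode_corepressed	11	193
mode_suppressed_activation	83	193
mode_relieved_repression	3	193
kb_only_genes_hs_affected	293	3665
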