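id	equation	gpr	lb	ub	subsystem	objective
EX_a1	a1[e] <=> 		-10	1000	exchange	FALSE
T_a1	a1[e] => a1[c]	g_T_a1_1	0	1000	transport	FALSE
R1_1	a1[c] => m1_1[c]	g_R1_1_1 or g_R1_1_2	0	1000	pathway_1	FALSE
R1_2	m1_1[c] => m1_2[c]	g_R1_2_1	0	1000	pathway_1	FALSE
R1_3	m1_2[c] => p1[c]	(g_R1_3_1 or g_R1_3_2) and g_R1_3_3	0	1000	pathway_1	FALSE
T_p1	p1[c] => p1[e]	g_T_p1_1 or g_T_p1_2	0	1000	transport	FALSE
EX_p1	p1[e] => 		0	1000	exchange	FALSE
EX_a2	a2[e] <=> 		-10	1000	exchange	FALSE
T_a2	a2[e] => a2[c]	g_T_a2_1 or g_T_a2_2	0	1000	transport	FALSE
R2_1	a2[c] <=> m2_1[c]	g_R2_1_1	-1000	1000	pathway_2	FALSE
R2_2	m2_1[c] <=> m2_2[c]	g_R2_2_1 or g_R2_2_2	-1000	1000	pathway_2	FALSE
R2_3	m2_2[c] => p2[c]	g_R2_3_1 and g_R2_3_2	0	1000	pathway_2	FALSE
T_p2	p2[c] => p2[e]	g_T_p2_1 or g_T_p2_2	0	1000	transport	FALSE
EX_p2	p2[e] => 		0	1000	exchange	FALSE
biomass	0.5 p1[c] + 0.5 p2[c] => bm[c]		0	1000	biomass	TRUE
EX_bm	bm[c] => 		0	1000	exchange	FALSE
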