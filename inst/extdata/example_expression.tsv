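gene	log2fc	qvalue
g_R1_1_1	2	0.01
g_R1_1_2	2	0.01
g_R1_2_1	2	0.01
g_R1_3_1	2	0.01
g_R1_3_2	2	0.01
g_R1_3_3	2	0.01
g_T_a1_1	2	0.01
g_T_p1_1	2	0.01
g_T_p1_2	2	0.01
g_R2_1_1	0.571811790335131	0.5
g_R2_2_1	-0.299192920555587	0.5
g_R2_2_2	-0.173573127608865	0.5
g_R2_3_1	-0.103073237784201	0.5
g_R2_3_2	-0.242668335279871	0.5
g_T_a2_1	-0.236819986307027	0.5
g_T_a2_2	0.187034835072638	0.5
g_T_p2_1	-0.0292388064717879	0.5
g_T_p2_2	0.0381644065705584	0.5
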