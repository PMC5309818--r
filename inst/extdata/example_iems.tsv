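iem_id	genes	biomarker	direction
toy_deficiency	g_R1_1_1;g_R1_1_2	p1[e]	reduced
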