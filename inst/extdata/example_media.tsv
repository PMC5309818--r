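reaction	lb	ub
EX_a1	-10	1000
EX_a2	-10	1000
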