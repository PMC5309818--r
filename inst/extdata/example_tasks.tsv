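TASK secrete_p1 make pathway-1 product from its substrate
IN a1[e] 0 10
OUT p1[e] 1 10

TASK p1_from_nothing impossible without uptake
OUT p1[e] 1 10
SHOULD_FAIL
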