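pA	m2	1
pA	m3	1
pB	m2	1
pB	m8	1
pE	m4	1
pF	m4	1
pE	m7	1
pG	m6	1
pC	m1	-1
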