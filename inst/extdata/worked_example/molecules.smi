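m1	C
m2	CC
m3	CCO
m4	c1ccccc1
m5	O
m6	CCN
m7	CC(=O)O
m8	CCC
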