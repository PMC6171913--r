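pA	enzymes/classA/pA
pB	enzymes/classA/pB
pC	enzymes/classB/pC
pD	enzymes/classB/pD
pE	receptors/classC/pE
pF	receptors/classC/pF
pG	receptors/classD/pG
pH	receptors/classD/pH
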