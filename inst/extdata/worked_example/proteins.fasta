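>pA example protein
ACDE
>pB
AAAA
>pC
CCCC
>pD
A
>pE
ACDEFGHIK
>pF
MKTAYIAKQR
>pG
ACDF
>pH
WYYW
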