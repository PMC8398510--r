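actual,SA,EE,EF,SER,SIR,SE,SF
SA,88,2,2,5,,,3
EE,,95,4,,1,,
EF,,,98,,,,2
SER,8,,,91,,1,
SIR,,,,,98,,2
SE,,,,,,96,
SF,7,,,,,,93
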