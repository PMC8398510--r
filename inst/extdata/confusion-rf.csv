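actual,SA,EE,EF,SER,SIR,SE,SF
SA,94,,,,,,6
EE,,98,,,2,,
EF,,,97,,,,3
SER,,,,97,,3,
SIR,,,1,1,98,,
SE,,,,2,,98,
SF,4,,,,,,96
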