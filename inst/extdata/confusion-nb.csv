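actual,SA,EE,EF,SER,SIR,SE,SF
SA,98,,,,,1,1
EE,,95,4,,1,,
EF,,,99,,,1,
SER,1,2,,97,,,
SIR,,1,,,99,,
SE,,6,,,4,90,
SF,12,8,,,,,80
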