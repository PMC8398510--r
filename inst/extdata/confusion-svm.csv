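actual,SA,EE,EF,SER,SIR,SE,SF
SA,96,1,,,,,3
EE,,99,,,1,,
EF,,,99,,,1,
SER,9,2,,89,,,
SIR,1,2,,,97,,
SE,,,3,3,,94,
SF,10,,,,,,90
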