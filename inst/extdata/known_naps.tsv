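name	locus_tag
HupA	SCO2950
HupS	SCO5556
sIHF	SCO1480
Lsr2	SCO3375
BldD	SCO1489
CRP	SCO3571
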