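source	target
TNF	Tnf
TNFRSF1A	Tnfrsf1a
IL1B	Il1b
IL1R1	Il1r1
TGFB1	Tgfb1
TGFBR1	Tgfbr1
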