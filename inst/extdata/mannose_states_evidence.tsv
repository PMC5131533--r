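strain	gene	state	note
B16	manB	S	singular IIC subunit mutation in the five mannose-negative strains
IOEB_0205	manB	S	singular IIC subunit mutation in the five mannose-negative strains
AWRI_B548	manB	S	singular IIC subunit mutation in the five mannose-negative strains
S25	manB	S	singular IIC subunit mutation in the five mannose-negative strains
IOEB_0607	manB	S	singular IIC subunit mutation in the five mannose-negative strains
ATCC_BAA-1163	manA	P	manA truncated in a mannose-positive strain
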