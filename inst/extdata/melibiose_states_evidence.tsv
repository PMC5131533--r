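strain	gene	state	note
S28	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
S23	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
AWRI_B429	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
IOEB_0608	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
IOEB_9517	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
IOEB_L65.2	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
B16	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
IOEB_0205	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
AWRI_B548	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
CiNe	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
S25	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
IOEB_0607	galA	P	melibiase annotated as pseudogene (12 strains; positive carriers assumed)
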