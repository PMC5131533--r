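strain	gene	state	note
IOEB_B10	manC	I	complete and putatively functional manC
S13	manC	I	complete and putatively functional manC
S12	manC	I	complete and putatively functional manC
IOEB_0501	manC	I	complete and putatively functional manC
IOEB_0502	manC	I	complete and putatively functional manC
IOEB_9803	manC	I	complete and putatively functional manC
IOEB_9805	manC	I	complete and putatively functional manC
IOEB_8417	manC	I	complete and putatively functional manC
IOEB_9304	manC	I	complete and putatively functional manC
IOEB_C28	manC	I	complete and putatively functional manC
S28	manC	P	manC present in truncated form (20 strains; membership assumed)
S23	manC	P	manC present in truncated form (20 strains; membership assumed)
S11	manC	P	manC present in truncated form (20 strains; membership assumed)
AWRI_B429	manC	P	manC present in truncated form (20 strains; membership assumed)
CiNe	manC	P	manC present in truncated form (20 strains; membership assumed)
IOEB_0608	manC	P	manC present in truncated form (20 strains; membership assumed)
IOEB_9517	manC	P	manC present in truncated form (20 strains; membership assumed)
IOEB_L65.2	manC	P	manC present in truncated form (20 strains; membership assumed)
AWRI_B419	manC	P	manC present in truncated form (20 strains; membership assumed)
VF	manC	P	manC present in truncated form (20 strains; membership assumed)
IOEB_S436a	manC	P	manC present in truncated form (20 strains; membership assumed)
S15	manC	P	manC present in truncated form (20 strains; membership assumed)
S161	manC	P	manC present in truncated form (20 strains; membership assumed)
IOEB_S277	manC	P	manC present in truncated form (20 strains; membership assumed)
IOEB_L18.3	manC	P	manC present in truncated form (20 strains; membership assumed)
S19	manC	P	manC present in truncated form (20 strains; membership assumed)
IOEB_1491	manC	P	manC present in truncated form (20 strains; membership assumed)
AWRI_B129	manC	P	manC present in truncated form (20 strains; membership assumed)
IOEB_L40.4	manC	P	manC present in truncated form (20 strains; membership assumed)
IOEB_S450	manC	P	manC present in truncated form (20 strains; membership assumed)
PSU-1	manC	A	manC absent (11 strains; membership assumed)
S14	manC	A	manC absent (11 strains; membership assumed)
B16	manC	A	manC absent (11 strains; membership assumed)
IOEB_0205	manC	A	manC absent (11 strains; membership assumed)
AWRI_B548	manC	A	manC absent (11 strains; membership assumed)
IOEB_0607	manC	A	manC absent (11 strains; membership assumed)
S25	manC	A	manC absent (11 strains; membership assumed)
IOEB_L26.1	manC	A	manC absent (11 strains; membership assumed)
ATCC_BAA-1163	manC	A	manC absent (11 strains; membership assumed)
IOEB_C23	manC	A	manC absent (11 strains; membership assumed)
IOEB_C52	manC	A	manC absent (11 strains; membership assumed)
S19	fruA	I	pts-fructose cluster (cluster assignment assumed)
IOEB_1491	fruA	I	pts-fructose cluster (cluster assignment assumed)
ATCC_BAA-1163	fruB	I	pts-fructose cluster (cluster assignment assumed)
S12	fruB	I	pts-fructose cluster (cluster assignment assumed)
IOEB_C23	fruC	I	pts-fructose cluster (cluster assignment assumed)
IOEB_C52	fruD	I	pts-fructose cluster (cluster assignment assumed)
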