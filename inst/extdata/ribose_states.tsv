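strain	ribT	mfs9C23	ribK	ribK1	ribA	ribA1	mfs148
S28	I	A	I	I	I	I	I
S23	I	A	I	I	I	I	I
S11	I	A	I	I	I	I	I
AWRI_B429	I	A	I	I	I	I	I
CiNe	I	A	I	I	I	I	I
IOEB_0608	I	A	I	I	I	I	I
IOEB_9517	I	A	I	I	I	I	I
IOEB_L65.2	I	A	I	I	I	I	I
AWRI_B419	I	A	I	I	I	I	I
VF	I	A	I	I	I	I	I
IOEB_S436a	I	A	I	I	I	I	I
S15	I	A	I	I	I	I	I
S161	I	A	I	I	I	I	I
IOEB_S277	I	A	I	I	I	I	I
IOEB_L18.3	I	A	I	I	I	I	I
IOEB_B10	P	A	I	I	I	I	I
S19	P	A	I	I	I	I	I
IOEB_1491	P	A	I	I	I	I	I
AWRI_B129	I	A	I	I	I	I	I
IOEB_L40.4	I	A	I	I	I	I	I
IOEB_S450	I	A	I	I	I	I	I
PSU-1	I	A	I	I	I	I	I
S14	I	A	I	I	I	I	I
B16	I	A	I	I	I	I	I
IOEB_0205	I	A	I	I	I	I	I
AWRI_B548	I	A	I	I	I	I	I
IOEB_0607	I	A	I	I	I	I	I
S25	P	A	I	I	I	I	I
IOEB_L26.1	I	A	I	I	I	I	I
S13	I	A	I	I	I	I	I
S12	I	A	I	I	I	I	I
IOEB_0501	I	A	I	I	I	I	I
IOEB_0502	I	A	I	I	I	I	I
ATCC_BAA-1163	I	A	I	I	I	I	I
IOEB_9803	I	A	I	I	I	I	I
IOEB_9805	I	A	I	I	I	I	I
IOEB_8417	I	A	I	I	I	I	I
IOEB_9304	I	A	I	I	I	I	I
IOEB_C28	I	A	I	I	I	I	I
IOEB_C23	A	I	I	I	I	I	I
IOEB_C52	I	A	I	I	I	I	I
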