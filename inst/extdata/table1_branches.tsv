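strain	branch
S28	A
S23	A
S11	A
AWRI_B429	A
CiNe	A
IOEB_0608	A
IOEB_9517	A
IOEB_L65.2	A
AWRI_B419	A
VF	A
IOEB_S436a	A
S15	A
S161	A
IOEB_S277	A
IOEB_L18.3	A
IOEB_B10	A
S19	A
IOEB_1491	A
AWRI_B129	A
IOEB_L40.4	A
IOEB_S450	A
PSU-1	A
S14	A
B16	A
IOEB_0205	A
AWRI_B548	A
IOEB_0607	A
S25	A
IOEB_L26.1	A
S13	B
S12	B
IOEB_0501	B
IOEB_0502	B
ATCC_BAA-1163	B
IOEB_9803	B
IOEB_9805	B
IOEB_8417	B
IOEB_9304	B
IOEB_C28	B
IOEB_C23	B
IOEB_C52	C
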