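variant	canonical
AWRIB_429	AWRI_B429
AWRIB-429	AWRI_B429
ATCC_BAA1163	ATCC_BAA-1163
ATCC BAA-1163	ATCC_BAA-1163
IOEB_L65_2	IOEB_L65.2
IOEB_L40_4	IOEB_L40.4
Cine	CiNe
B10	IOEB_B10
C23	IOEB_C23
C28	IOEB_C28
C52	IOEB_C52
IOEB 0607	IOEB_0607
IOEB_S436	IOEB_S436a
S436a	IOEB_S436a
IOEB 9803	IOEB_9803
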