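strain	gene	state	note
IOEB_1491	ribT	P	ribT truncated by mutation; ribose phenotype negative
IOEB_B10	ribT	P	ribT truncated by mutation; ribose phenotype negative
S25	ribT	P	ribT truncated by mutation; ribose phenotype negative
S19	ribT	P	ribT truncated by mutation; ribose phenotype negative
IOEB_C23	ribT	A	ribT lost through 3' reorganization of the ribose1 cluster
IOEB_C23	mfs9C23	I	strain-specific ribose permease explaining the positive phenotype
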