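strain	gene	state	note
IOEB_0501	malA	I	maltose-trehalose phosphorylase pathway complete and potentially active
S13	malA	I	maltose-trehalose phosphorylase pathway complete and potentially active
IOEB_C23	malA	I	maltose-trehalose phosphorylase pathway complete and potentially active
IOEB_9304	malA	I	maltose-trehalose phosphorylase pathway complete and potentially active
S12	malA	I	maltose-trehalose phosphorylase pathway complete and potentially active
IOEB_C52	malA	I	maltose-trehalose phosphorylase pathway complete and potentially active
IOEB_9803	malA	I	maltose-trehalose phosphorylase pathway complete and potentially active
IOEB_9805	malA	I	maltose-trehalose phosphorylase pathway complete and potentially active
IOEB_0502	malA	P	malA truncated despite positive maltose phenotype
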