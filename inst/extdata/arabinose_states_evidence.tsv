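strain	gene	state	note
AWRI_B429	araA	P	araA truncated; phenotype negative, no rescue
ATCC_BAA-1163	araA	P	araA truncated; phenotype negative, no rescue
IOEB_S450	araB	P	araB truncated; phenotype negative, no rescue
ATCC_BAA-1163	araB	P	araB truncated; phenotype negative, no rescue
IOEB_0607	araD	P	araD truncated
AWRI_B419	araD	P	araD truncated
AWRI_B419	araD1	I	cluster-B isomerase rescues truncated araD
S23	epi	P	epimerase absent or disrupted without phenotype change
S11	epi	P	epimerase absent or disrupted without phenotype change
S15	epi	P	epimerase absent or disrupted without phenotype change
S13	epi	P	epimerase absent or disrupted without phenotype change
IOEB_L40.4	epi	P	epimerase absent or disrupted without phenotype change
S28	araC	P	regulator mutated without phenotype change
IOEB_9805	araC	P	regulator mutated without phenotype change
IOEB_0501	araC	P	regulator mutated without phenotype change
IOEB_9304	araT	A	transporter absent or mutated without phenotype change
IOEB_C28	araT	A	transporter absent or mutated without phenotype change
IOEB_C52	araT	A	transporter absent or mutated without phenotype change
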