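strain	gene	state	note
ATCC_BAA-1163	treC	P	phosphotrehalase in locus treA truncated without phenotype change
S13	treC	P	phosphotrehalase in locus treA truncated without phenotype change
AWRI_B419	treC	P	phosphotrehalase in locus treA truncated without phenotype change
IOEB_0607	ptsEI	S	EI mutated near the active site in the single trehalose-negative strain
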