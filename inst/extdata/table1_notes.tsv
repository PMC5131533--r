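item	note
melibiose branch-A negatives beyond prose	S28/S23/0608/9517/L65.2 chosen negative to satisfy row and column totals
arabinose branch-A positives beyond named strains	VF/IOEB_S436a/S161/IOEB_S277/PSU-1/IOEB_0608 chosen positive to reach the printed 23
galactose positives	S15/S12/IOEB_0501/IOEB_0502 chosen to satisfy row totals (4 positives printed)
raffinose positives	S161/IOEB_0501 chosen to satisfy row totals (2 positives printed)
branch-B sucrose/maltose membership beyond named strains	assignment satisfies row totals, 8 maltose and 9 sucrose positives, none in branch A
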