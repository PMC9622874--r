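layer	id	degree	in_final_network
mrna	INSR	NA	TRUE
mrna	NOS3	NA	TRUE
mrna	PPARG	NA	TRUE
mrna	SLC2A4	NA	TRUE
mrna	SOD2	NA	TRUE
mrna	HMOX1	NA	TRUE
mrna	TNF	NA	TRUE
mrna	INS	0	FALSE
mrna	LEP	0	FALSE
mirna	hsa-miR-3184-5p	4	TRUE
mirna	hsa-miR-17-5p	4	TRUE
mirna	hsa-miR-20a-5p	4	TRUE
mirna	hsa-miR-93-5p	4	TRUE
mirna	hsa-miR-106b-5p	4	TRUE
mirna	hsa-miR-20b-5p	4	TRUE
mirna	hsa-miR-200c-3p	4	TRUE
lncrna	NEAT1	7	TRUE
lncrna	XIST	7	TRUE
lncrna	EBLN3P	7	TRUE
lncrna	H19	6	TRUE
lncrna	MALAT1	6	TRUE
lncrna	HCG18	6	TRUE
lncrna	PSMA3-AS1	6	TRUE
lncrna	AC021078.1	6	TRUE
lncrna	AC005261.1	6	TRUE
lncrna	AC024940.6	6	TRUE
lncrna	NORAD	6	TRUE
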