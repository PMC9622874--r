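lncrna	direction_dm	direction_ad	mechanism
NEAT1	up	up	Biomarker in DM and AD
XIST	up	up	Biomarker in DM and AD
HCG18	up	up	Insulin resistance
EBLN3P	up	up	Increasing the risk of type 1 diabetes mellitus
H19	up	up	Apoptosis of hippocampal neurons
MALAT1	down	down	Reduced anti-apoptotic effect
PSMA3-AS1	unknown	unknown	Novel
AC021078.1	unknown	unknown	Novel
AC005261.1	unknown	unknown	Novel
AC024940.6	unknown	unknown	Novel
NORAD	unknown	unknown	Novel
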