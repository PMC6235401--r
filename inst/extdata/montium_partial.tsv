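species	kl-2	kl-3	kl-5	PRY	PPr-Y	ORY	WDY	Pp1-Y1	Pp1-Y2	ARY	JY-alpha	CG11719	CG2964	CG14339	CG18155
auraria	MF	MF	MF	MF	MF	MF	MF	MF	MF	MF	MF	MF	MF	MF	MF
kikkawai	M	NA	NA	NA	NA	NA	M	NA	NA	NA	NA	MF	MF	MF	MF
parvula	NA	NA	M	M	NA	NA	NA	NA	NA	NA	NA	MF	MF	MF	MF
kanapiae	NA	NA	M	M	NA	NA	NA	NA	NA	NA	NA	MF	MF	MF	MF
nikananu	NA	NA	M	M	NA	M	NA	NA	NA	M	NA	MF	MF	MF	MF
diplacantha	NA	NA	MF	MF	NA	MF	NA	NA	NA	MF	NA	MF	MF	MF	MF
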