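species	ORY
mel	M
vir	M
aca	M
nan	MF
imm	M
afr	MF
bog	MF
dav	MF
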