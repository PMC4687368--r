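type	phi1	psi1	phi2	psi2
I	-60	-30	-90	0
Ip	60	30	90	0
II	-60	120	80	0
IIp	60	-120	-80	0
IV	-61	10	-53	17
VIII	-60	-30	-120	120
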