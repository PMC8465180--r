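gene	group	m0_printed	sem_printed
Ascl3	aggressive	0.26	0.12
Ascl3	tame	2.04	0.52
Apobec1	aggressive	0.88	0.28
Apobec1	tame	3.17	1.07
Defb17	aggressive	0.01	0.01
Defb17	tame	1.33	0.35
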