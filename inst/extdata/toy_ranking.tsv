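gene	score
G01	2.8
G02	2.3
G03	1.9
G04	1.6
G05	1.2
G06	0.9
G07	0.7
G08	0.5
G09	0.35
G10	0.2
G11	-0.1
G12	-0.3
G13	-0.5
G14	-0.8
G15	-1.0
G16	-1.3
G17	-1.7
G18	-2.0
G19	-2.4
G20	-2.9
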