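quantitative	<30	30-300	>=300
<30	187	68	0
30-300	8	38	0
>=300	0	0	0
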