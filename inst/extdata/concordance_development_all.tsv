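quantitative	<30	30-300	>=300
<30	664	408	9
30-300	52	350	78
>=300	0	17	303
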