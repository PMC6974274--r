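quantitative	<30	30-300	>=300
<30	579	333	5
30-300	36	142	8
>=300	0	2	5
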