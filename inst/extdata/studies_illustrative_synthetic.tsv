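study_id	outcome	hr	ci_low	ci_high
synthetic_01	death	1.502	1.1915	1.8935
synthetic_02	death	1.5376	1.3962	1.6933
synthetic_03	death	1.9798	1.3669	2.8677
synthetic_04	death	1.5439	1.0889	2.1889
synthetic_05	death	1.3666	1.1401	1.6381
synthetic_06	death	1.2089	0.9879	1.4794
synthetic_07	death	1.9821	1.4406	2.7273
synthetic_08	death	1.5562	1.2543	1.9307
synthetic_09	death	1.7143	1.227	2.395
synthetic_01	CVD	1.817	1.3278	2.4865
synthetic_02	CVD	1.5754	1.1892	2.0871
synthetic_03	CVD	1.6825	1.1267	2.5124
synthetic_04	CVD	1.5101	1.1178	2.04
synthetic_05	CVD	1.3338	1.1893	1.4957
synthetic_06	CVD	1.4104	1.0968	1.8138
synthetic_01	ESRD	2.7206	2.0746	3.5677
synthetic_02	ESRD	3.0398	2.5132	3.6767
synthetic_03	ESRD	3.0495	1.9779	4.7016
synthetic_04	ESRD	2.999	1.964	4.5795
synthetic_05	ESRD	3.9477	3.1663	4.9219
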