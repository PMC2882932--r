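protein_id	start	window	raw_score	norm_score	conservation	accessibility	disorder	hits_per_protein	posterior	supporting_hits
T1	3	APTK	60	1	1	0.8	0.9	9	1	9
T5	3	APSK	50	0.8333333333	1	0.8	0.9	9	1	9
T2	3	CPSK	40	0.6666666667	1	0.8	0.9	9	1	9
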