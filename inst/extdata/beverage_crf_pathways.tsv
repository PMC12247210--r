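exposure	mediator	outcome	beta1	b1_lo	b1_hi	beta2	b2_lo	b2_hi	beta_all	ball_lo	ball_hi
alcohol	op_ratio	crf	-0.1822	-0.3431	-0.0213	-0.1823	-0.2830	-0.0816	0.2429	0.0453	0.4405
alcohol	x23655	crf	-0.1948	-0.3765	-0.0130	0.1119	0.0317	0.1920	0.2429	0.0453	0.4405
tea	mcs	crf	1.6036	0.4504	2.7569	0.1276	0.0528	0.2024	-0.7951	-1.5928	0.0026
tea	glutarate	crf	-1.0900	-1.8395	-0.3405	-0.1065	-0.1804	-0.0325	-0.7951	-1.5928	0.0026
tea	salicylate	crf	0.8192	0.0945	1.5438	-0.1215	-0.2054	-0.0375	-0.7951	-1.5928	0.0026
tea	x23655	crf	1.3316	0.0535	2.6096	0.1119	0.0317	0.1920	-0.7951	-1.5928	0.0026
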