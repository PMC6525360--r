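genotype	net	replicate	outcrossing_rate
CNL1_G	Bird	1	0.36
CNL1_G	Bird	2	0.29
CNL1_G	Bird	3	0.25
CNL1_R	Bird	1	0.18
CNL1_R	Bird	2	0.16
CNL1_R	Bird	3	0.35
CNL1_G	Insect	1	0.01
CNL1_G	Insect	2	0
CNL1_G	Insect	3	0.08
CNL1_R	Insect	1	0.03
CNL1_R	Insect	2	0
CNL1_R	Insect	3	0
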