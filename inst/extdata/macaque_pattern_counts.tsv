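analysis	bbaa	abba	baba
X_depth_genotyped	40304	3781	2014
X_male_het_filtered	39825	1938	1667
autosomes	1203957	145277	144491
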