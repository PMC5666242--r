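analysis	cbba	bcba	ccba
X_depth_genotyped	135	138	360
X_male_het_filtered	85	93	106
autosomes	5212	5265	7636
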