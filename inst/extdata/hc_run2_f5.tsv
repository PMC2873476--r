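sample	amplicon	direction_class	haplotype	count
NA12760	F5	forward_partial	TCC	7399
NA12760	F5	forward_partial	CCC	1765
NA12760	F5	forward_partial	CTG	1591
NA12760	F5	reverse_partial	CCGGGC	14683
NA12760	F5	reverse_partial	CCGGAC	2891
NA12760	F5	reverse_partial	TGGGAC	2895
NA18502	F5	forward_partial	TCC	8307
NA18502	F5	forward_partial	CCC	1069
NA18502	F5	forward_partial	CCG	1006
NA18502	F5	reverse_partial	CCGGGC	17586
NA18502	F5	reverse_partial	CCGGGA	1764
NA18502	F5	reverse_partial	CGGGAC	1950
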