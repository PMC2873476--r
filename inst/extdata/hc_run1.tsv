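sample	amplicon	direction_class	haplotype	count
C0140	F2	full	GA	1566
C0140	F2	full	GG	583
C0140	F2	full	CA	528
C0140	F5	forward_partial	TCC	664
C0140	F5	reverse_partial	CCGGGC	1491
C0140	F5	reverse_partial	CCGAGC	431
C0140	F4	full	TAT	582
C0140	F4	full	CAT	390
C0140	F4	full	TAC	382
C0140	F6	full	CCTCG	867
C0140	F6	full	CCTAG	816
C0140	F7	full	TCG	888
C0140	F7	full	TTA	288
C0140	F8	full	CTACCG	542
C0140	F8	full	TCTTTA	195
C0766	F2	full	GG	1525
C0766	F2	full	CA	842
C0766	F5	forward_partial	TCC	360
C0766	F5	forward_partial	CCC	195
C0766	F5	reverse_partial	CCGGGC	1084
C0766	F5	reverse_partial	CCGGAC	506
C0766	F4	full	TAC	1679
C0766	F4	full	CAT	601
C0766	F7	full	TCG	1878
C0766	F8	full	CTACCG	876
C0913	F2	full	CA	1869
C0913	F2	full	GA	1157
C0913	F5	forward_partial	TCC	680
C0913	F5	forward_partial	CCC	287
C0913	F5	reverse_partial	CCGGGC	1221
C0913	F5	reverse_partial	CCGGAC	617
C0913	F4	full	TAC	1556
C0913	F4	full	TCC	634
C0913	F6	full	CCTCG	1195
C0913	F6	full	CCTAG	593
C0913	F7	full	TCG	1816
C0913	F8	full	CTACCG	2153
NA12760	F2	full	GA	1750
NA12760	F2	full	GG	386
NA12760	F2	full	CA	319
NA12760	F5	forward_partial	TCC	795
NA12760	F5	forward_partial	CCC	181
NA12760	F5	forward_partial	CTG	184
NA12760	F5	reverse_partial	CCGGGC	1566
NA12760	F5	reverse_partial	CCGGAC	339
NA12760	F5	reverse_partial	TGGGAC	459
NA12760	F4	full	TAC	2825
NA12760	F4	full	TAT	981
NA12760	F4	full	TCC	797
NA12760	F6	full	CCTCG	1669
NA12760	F6	full	CTCAC	599
NA12760	F6	full	CCTAG	499
NA12760	F7	full	TTA	2056
NA12760	F7	full	TCG	1696
NA12760	F8	full	TCTTTA	645
NA12760	F8	full	CTACCG	605
NA15029	F2	full	GA	1530
NA15029	F2	full	GG	805
NA15029	F5	forward_partial	TCC	767
NA15029	F5	forward_partial	CTG	475
NA15029	F5	reverse_partial	CCGGGC	1046
NA15029	F5	reverse_partial	CCAGGC	431
NA15029	F5	reverse_partial	TGGGAC	913
NA15029	F4	full	TCC	1156
NA15029	F4	full	TAT	882
NA15029	F4	full	TAC	496
NA15029	F4	full	CAT	420
NA15029	F6	full	CCTGC	1785
NA15029	F6	full	CTCAT	1087
NA15029	F7	full	TTA	1689
NA15029	F7	full	TCG	1115
NA15029	F8	full	TCTTTA	377
NA15029	F8	full	CTACCG	267
NA15213	F2	full	GA	1326
NA15213	F2	full	CA	349
NA15213	F5	forward_partial	TCC	665
NA15213	F5	forward_partial	CTG	171
NA15213	F5	reverse_partial	CCGGGC	1338
NA15213	F5	reverse_partial	TGGGAC	390
NA15213	F4	full	TAC	278
NA15213	F4	full	TAT	98
NA15213	F4	full	TCC	87
NA15213	F6	full	CCTCG	1178
NA15213	F6	full	CCTAG	577
NA15213	F6	full	CTCAT	473
NA15213	F7	full	TCG	1496
NA15213	F7	full	TTA	866
NA15213	F8	full	CTACCG	929
NA15213	F8	full	TCTTTA	551
NA15385	F2	full	GA	985
NA15385	F2	full	GG	592
NA15385	F5	forward_partial	TCC	374
NA15385	F5	forward_partial	CCC	169
NA15385	F5	forward_partial	CTG	88
NA15385	F5	reverse_partial	CCGGGC	702
NA15385	F5	reverse_partial	CCGGAC	239
NA15385	F5	reverse_partial	TGGGAC	188
NA15385	F4	full	TAC	1374
NA15385	F4	full	TAT	673
NA15385	F4	full	TCC	345
NA15385	F6	full	CCTCG	1003
NA15385	F6	full	CCTAG	322
NA15385	F6	full	CTCAT	280
NA15385	F7	full	TCG	938
NA15385	F7	full	TTA	782
NA15385	F8	full	CTACCG	688
NA15385	F8	full	TCTTTA	483
NA18502	F2	full	GA	812
NA18502	F2	full	CA	561
NA18502	F5	forward_partial	TCC	182
NA18502	F5	forward_partial	CCC	21
NA18502	F5	forward_partial	CCG	7
NA18502	F5	reverse_partial	CCGGGC	265
NA18502	F5	reverse_partial	CCGGGA	56
NA18502	F5	reverse_partial	CGGGAC	39
NA18502	F4	full	TAT	1453
NA18502	F6	full	CCTCG	415
NA18502	F6	full	TTCAT	65
NA18502	F7	full	TTA	856
NA18502	F7	full	TCG	418
NA18502	F8	full	TCTTTA	645
NA18502	F8	full	CTACCG	267
NA18552	F2	full	CA	3490
NA18552	F5	forward_partial	TCC	197
NA18552	F5	forward_partial	CCC	328
NA18552	F5	reverse_partial	CCGGGC	273
NA18552	F5	reverse_partial	CCGGAC	340
NA18552	F4	full	TAT	225
NA18552	F4	full	TAC	1058
NA18552	F4	full	CAT	503
NA18552	F6	full	CCTCG	1653
NA18552	F7	full	TCG	1756
NA18552	F8	full	CTACCG	1525
NA18858	F2	full	GA	677
NA18858	F2	full	CA	324
NA18858	F2	full	GG	205
NA18858	F5	forward_partial	TCC	1234
NA18858	F5	reverse_partial	CCGGGC	623
NA18858	F5	reverse_partial	CCGAGC	218
NA18858	F4	full	TAT	1490
NA18858	F4	full	TAC	822
NA18858	F6	full	CCTCG	1327
NA18858	F7	full	TTA	1087
NA18858	F7	full	TCG	404
NA18858	F8	full	TCTTTA	2404
NA18858	F8	full	CTACCG	633
NA19140	F2	full	GA	314
NA19140	F2	full	CA	310
NA19140	F2	full	GG	105
NA19140	F5	forward_partial	TCC	706
NA19140	F5	reverse_partial	CCGGGC	234
NA19140	F5	reverse_partial	CCGAGC	42
NA19140	F6	full	CCTCG	504
NA19140	F6	full	CTCAT	130
NA19140	F7	full	TTA	281
NA19140	F7	full	TCG	62
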