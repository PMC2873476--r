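sample	method	cn
C0140	MAPH_REDVR	4
C0140	5PRT	3.78
C0140	PPRT	4.19
C0140	MLPA	4
C0766	MAPH_REDVR	3
C0766	5PRT	2.75
C0766	PPRT	3.31
C0766	MLPA	3
C0913	MAPH_REDVR	3
C0913	5PRT	3.00
C0913	PPRT	3.13
C0913	MLPA	3
NA12760	MAPH_REDVR	6
NA12760	5PRT	5.57
NA12760	PPRT	6.04
NA12760	MLPA	6
NA15029	5PRT	4.70
NA15029	PPRT	5.58
NA15029	MLPA	5
NA15213	5PRT	4.18
NA15213	PPRT	4.18
NA15213	MLPA	4
NA15385	5PRT	5.29
NA15385	PPRT	5.17
NA15385	MLPA	5
NA18502	MAPH_REDVR	8
NA18502	5PRT	8.98
NA18502	MLPA	9
NA18552	MAPH_REDVR	2
NA18552	5PRT	2.23
NA18552	PPRT	2.02
NA18552	MLPA	2
NA18858	MAPH_REDVR	8
NA18858	5PRT	7.71
NA18858	PPRT	8.08
NA18858	MLPA	8
NA19140	MAPH_REDVR	7
NA19140	5PRT	5.71
NA19140	PPRT	6.26
NA19140	MLPA	6
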