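cohort	gleason	count
Taylor	3+3	41
Taylor	3+4	53
Taylor	3+5	1
Taylor	4+3	23
Taylor	4+4	8
Taylor	4+5	10
Taylor	5+3	2
TCGA	3+3	38
TCGA	3+4	121
TCGA	3+5	7
TCGA	4+3	80
TCGA	4+4	45
TCGA	4+5	88
TCGA	5+3	5
DKFZ	3+3	11
DKFZ	3+4	57
DKFZ	3+5	0
DKFZ	4+3	18
DKFZ	4+4	1
DKFZ	4+5	13
DKFZ	5+3	0
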