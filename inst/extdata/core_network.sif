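EIF4EBP1	-1	EIF4E
MAPK1	-1	EIF4EBP1
MAPK1	1	MKNK1
MAPK1	1	RPS6KA5
MKNK1	1	EIF4E
MTOR	-1	EIF4EBP1
RPS6KA5	-1	EIF4EBP1
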