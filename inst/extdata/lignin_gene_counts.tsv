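enzyme	count_a	count_b	printed_ratio
4CL	2	26	13.0
CCoAOMT	9	10	1.1
CCR	7	18	2.7
COMT	2	10	5.0
C4H	1	4	4.0
CAD	6	21	3.5
Laccase	5	23	4.6
AldOMT	1	7	7.0
DAHPS	2	8	4.0
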