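haplotype	count
A1d1a	99
A1a1	70
A1e	55
B1	40
A1b	35
A2	30
A1	28
A1d1	20
A1c	18
A1f	15
A4	14
A1d2	12
A5	12
B2	12
A1h	10
A6	10
C1	8
C2	7
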