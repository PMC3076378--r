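a	b	radius_um
2	1	7.35
3	1	13.91
4	2	10.13
5	3	7.78
6	2	7.91
7	6	6.9
8	7	12.69
9	5	6.61
10	8	6.61
11	7	11.09
12	8	8.46
6	10	13.49
1	8	9.58
4	12	11.82
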