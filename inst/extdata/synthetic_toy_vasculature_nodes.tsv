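id	x_um	y_um	z_um	role	pressure_mmhg	inflow_haematocrit
1	89	357	295.7	outlet	20.6288831413258	NA
2	261.4	55.2	111.6	interior	NA	NA
3	15.2	364.1	155.4	interior	NA	NA
4	36.4	4.3	327.2	interior	NA	NA
5	190.8	291.8	336.2	interior	NA	NA
6	98.7	140.1	93	outlet	21.5873599639162	NA
7	251.2	33.4	138.9	inlet	33.413010987686	0.45
8	123.8	333.4	96.2	interior	NA	NA
9	373.2	275.3	90.4	interior	NA	NA
10	133.1	369.6	7.1	interior	NA	NA
11	320.8	290.7	159.1	interior	NA	NA
12	136.4	255.9	43.1	inlet	34.350049816072	0.45
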