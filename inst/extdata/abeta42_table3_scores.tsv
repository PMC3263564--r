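position	residue	b_cell	t_cell
1	D	0.41	0.04
2	A	0.35	0.78
3	E	0.62	0.02
4	F	0.73	0.93
5	R	0.85	0.05
6	H	0.57	0.14
7	D	0.69	0.03
8	S	0.38	0.02
9	G	0.63	0.04
10	Y	0.56	0.96
11	E	0.58	0.02
12	V	0.35	0.9
13	H	-0.17	0.1
14	H	-0.66	0.11
15	Q	-1.03	0.03
16	K	-1.47	0.93
17	L	-1.34	0.95
18	V	-1.2	0.68
19	F	-0.93	0.69
20	F	-0.98	0.74
21	A	-0.82	0.05
22	E	-0.31	0.05
23	D	0.23	0.11
24	V	0.81	0.88
25	G	1.24	0.03
26	S	1.22	0.03
27	N	0.9	0.03
28	K	0.36	0.3
29	G	0.3	0.1
30	A	-0.24	0.05
31	I	-0.58	0.07
32	I	-1	0.13
33	G	-1.14	0.03
34	L	-1.19	0.72
35	M	-1.23	0.13
36	V	-1.16	0.23
37	G	-0.97	0.03
38	G	-1.02	0.03
39	V	-0.63	0.23
40	V	-0.45	0.33
41	I	-0.8	0.95
42	A	-1.06	0.83
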