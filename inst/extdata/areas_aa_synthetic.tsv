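section	area_cm2
1	0.40
2	0.45
3	0.55
4	0.70
5	0.90
6	1.10
7	1.20
8	1.20
9	1.10
10	1.00
11	0.90
12	0.90
13	1.00
14	1.10
15	1.20
16	1.40
17	1.70
18	2.00
19	2.40
20	2.80
21	3.20
22	3.60
23	4.00
24	4.40
25	4.80
26	5.20
27	5.60
28	6.00
29	6.20
30	6.40
31	6.40
32	6.20
33	6.00
34	5.80
35	5.50
36	5.20
37	5.00
38	4.80
39	4.60
40	4.40
41	4.20
42	4.00
43	3.80
44	3.60
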