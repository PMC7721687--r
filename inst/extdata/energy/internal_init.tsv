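size	dg
0	Inf
1	Inf
2	1
3	1
4	1.1
5	2
6	2
7	2.1
8	2.3
9	2.4
10	2.5
11	2.6
12	2.7
13	2.8
14	2.9
15	2.9
16	3
17	3.1
18	3.1
19	3.2
20	3.3
21	3.3
22	3.4
23	3.4
24	3.5
25	3.5
26	3.5
27	3.6
28	3.6
29	3.7
30	3.7
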