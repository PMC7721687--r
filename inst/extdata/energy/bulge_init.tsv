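size	dg
0	Inf
1	3.8
2	2.8
3	3.2
4	3.6
5	4
6	4.4
7	4.6
8	4.7
9	4.8
10	4.9
11	5
12	5.1
13	5.2
14	5.3
15	5.4
16	5.4
17	5.5
18	5.5
19	5.6
20	5.7
21	5.7
22	5.8
23	5.8
24	5.8
25	5.9
26	5.9
27	6
28	6
29	6
30	6.1
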