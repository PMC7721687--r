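size	dg
0	Inf
1	Inf
2	Inf
3	5.4
4	5.6
5	5.7
6	5.4
7	6
8	5.5
9	6.4
10	6.5
11	6.6
12	6.7
13	6.8
14	6.9
15	6.9
16	7
17	7.1
18	7.1
19	7.2
20	7.2
21	7.3
22	7.3
23	7.4
24	7.4
25	7.5
26	7.5
27	7.5
28	7.6
29	7.6
30	7.7
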