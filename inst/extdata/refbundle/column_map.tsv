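column	consensus_position
1	-76
2	-75
3	-74
4	-73
5	-72
6	-71
7	-70
8	-69
9	-68
10	-67
11	-66
12	-65
13	-64
14	-63
15	-62
16	-61
17	-60
18	-59
19	-58
20	-57
21	-56
22	-55
23	-54
24	-53
25	-52
26	-51
27	-50
28	-49
29	-48
30	-47
31	-46
32	-45
33	-44
34	-43
35	-42
36	-41
37	-40
38	-39
39	-38
40	-37
41	-36
42	-35
43	-34
44	-33
45	-32
46	-31
47	-30
48	-29
49	-28
50	-27
51	-26
52	-25
53	-24
54	-23
55	-22
56	-21
57	-20
58	-19
59	-18
60	-17
61	-16
62	-15
63	-14
64	-13
65	-12
66	-11
67	-10
68	-9
69	-8
70	-7
71	-6
72	-5
73	-4
74	-3
75	-2
76	-1
77	0
78	1
79	2
80	3
81	4
82	5
83	6
84	7
85	8
86	9
87	10
88	11
89	12
90	13
91	14
92	15
93	16
94	17
95	18
96	19
97	20
98	21
99	22
100	23
101	24
102	25
103	26
104	27
105	28
106	29
107	30
108	31
109	32
110	33
111	34
112	35
113	36
114	37
115	38
116	39
117	40
118	41
119	42
120	43
121	44
122	45
123	46
124	47
125	48
126	49
127	50
128	51
129	52
130	53
131	54
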