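# Synthetic reference feature map for the packaged ACD profile.
# Coordinates are reference-alignment columns (1-based).
# acd_start=55
# acd_end=146
# beta7_arg_column=126
column	feature
1	none
2	none
3	none
4	none
5	none
6	none
7	none
8	none
9	none
10	none
11	none
12	none
13	none
14	none
15	none
16	none
17	none
18	none
19	none
20	none
21	none
22	none
23	none
24	none
25	none
26	none
27	none
28	none
29	none
30	none
31	none
32	none
33	none
34	none
35	none
36	none
37	none
38	none
39	none
40	none
41	none
42	none
43	none
44	none
45	none
46	none
47	none
48	none
49	none
50	none
51	none
52	none
53	none
54	none
55	none
56	none
57	beta2
58	beta2
59	beta2
60	beta2
61	beta2
62	beta2
63	none
64	none
65	none
66	beta3
67	beta3
68	beta3
69	beta3
70	beta3
71	beta3
72	none
73	none
74	none
75	none
76	beta4
77	beta4
78	beta4
79	beta4
80	beta4
81	beta4
82	beta4
83	none
84	none
85	none
86	none
87	beta5
88	beta5
89	beta5
90	beta5
91	beta5
92	beta5
93	beta5
94	none
95	none
96	none
97	none
98	beta6
99	beta6
100	beta6
101	beta6
102	beta6
103	none
104	none
105	none
106	none
107	none
108	none
109	L57
110	L57
111	L57
112	L57
113	L57
114	L57
115	L57
116	L57
117	L57
118	L57
119	L57
120	L57
121	L57
122	none
123	beta7
124	beta7
125	beta7
126	beta7
127	beta7
128	beta7
129	beta7
130	none
131	none
132	beta8
133	beta8
134	beta8
135	beta8
136	beta8
137	beta8
138	none
139	none
140	beta9
141	beta9
142	beta9
143	beta9
144	beta9
145	none
146	none
147	none
148	none
149	none
150	none
151	none
152	none
153	none
154	none
155	none
156	none
157	none
158	none
159	none
160	none
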