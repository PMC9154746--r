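# glycan_profile Ns=200 normalized=true
1	1.3789316322084393e-103
2	4.611761622231265e-99
3	1.2175041911282824e-94
4	2.5371934189102779e-90
5	4.1736515217973045e-86
6	5.4194883985695171e-82
7	5.554946675533451e-78
8	4.4944959665804245e-74
9	2.8705267152195984e-70
10	1.44717712273596e-66
11	5.7591883394463003e-63
12	1.8091741398051466e-59
13	4.4862033857398655e-56
14	8.781264194145833e-53
15	1.3567962223181768e-49
16	1.6548235974036246e-46
17	1.5931926054641359e-43
18	1.2107775401227964e-40
19	7.2633994321230362e-38
20	3.4394974879994364e-35
21	1.2856701559584443e-32
22	3.7935309038513529e-30
23	8.8356232084598958e-28
24	1.6244645768391357e-25
25	2.3575602538964558e-23
26	2.7008151063833254e-21
27	2.4423415863715959e-19
28	1.7434016472974763e-17
29	9.8235395275962157e-16
30	4.369362120522667e-14
31	1.5340784845193726e-12
32	4.2516412893858106e-11
33	9.3013320877491656e-10
34	1.6062501531602665e-08
35	2.1895794637898621e-07
36	2.3560675486319245e-06
37	2.0012173585625624e-05
38	0.0001341776812239114
39	0.00071014298421498835
40	0.0029668173945131089
41	0.0097839748972266133
42	0.025469436719463747
43	0.052336279734286416
44	0.084891821699470696
45	0.10869469688081605
46	0.10985766289226294
47	0.087645950018681071
48	0.05519666615324427
49	0.027439319670563921
50	0.010767461523703673
51	0.003335283962012249
52	0.00081551470991425307
53	0.00015740201232756026
54	2.3981053556665067e-05
55	2.8840695877261562e-06
56	2.7379323190623376e-07
57	2.0517251353680452e-08
58	1.2136547136804844e-09
59	5.666966069392941e-11
60	2.0887457298422894e-12
61	6.0771511067712124e-14
62	1.3957061510778402e-15
63	2.5302733844832353e-17
64	3.6209322531591245e-19
65	4.0902783492062185e-21
66	3.6489201189862278e-23
67	1.9379065524454757e-24
68	1.3859898030737072e-22
69	9.3923047140188926e-21
70	5.2319822313931875e-19
71	2.3957297499574917e-17
72	9.0175149350115761e-16
73	2.790059040050863e-14
74	7.0960619014916856e-13
75	1.4835386868320766e-11
76	2.5495165505115979e-10
77	3.6015900173050438e-09
78	4.182232677397447e-08
79	3.9920832272427801e-07
80	3.132336863640578e-06
81	2.020295121360739e-05
82	0.00010711212796152995
83	0.00046680979312507061
84	0.0016723175533770228
85	0.0049246459952555976
86	0.011920892303420872
87	0.023720289802512447
88	0.038797942562587763
89	0.052164479653921424
90	0.057652552805726738
91	0.052376887113887161
92	0.039114546911314697
93	0.024011229729778011
94	0.01211624316455134
95	0.0050257286610649477
96	0.0017135925791554355
97	0.0004802789880947023
98	0.00011065144249558276
99	2.0955501163911452e-05
100	3.2622444601679702e-06
101	4.1745765737363286e-07
102	4.391226512858983e-08
103	3.7969661947152622e-09
104	2.6987664411981691e-10
105	1.5768293848169934e-11
106	7.5914784810772572e-13
107	3.6700922048276787e-14
108	2.498954120958041e-14
109	8.2341872007051807e-14
110	2.7389479212178756e-13
111	8.8482502422459323e-13
112	2.7752861316735778e-12
113	8.4515038999295421e-12
114	2.4988263901906282e-11
115	7.1732179821633984e-11
116	1.9992533393199535e-10
117	5.4100027838404725e-10
118	1.4213564479672682e-09
119	3.6256374688489939e-09
120	8.9792818889157329e-09
121	2.159109617547502e-08
122	5.0406162492382787e-08
123	1.1425321647091682e-07
124	2.5143694556988823e-07
125	5.3723661773321403e-07
126	1.1144946221393789e-06
127	2.244740824552186e-06
128	4.3896540007747062e-06
129	8.3343211551237521e-06
130	1.5363353738895985e-05
131	2.7496517054433112e-05
132	4.7779895809189121e-05
133	8.0609934422761837e-05
134	0.00013204069277240516
135	0.0002099920617645853
136	0.00032424539576722793
137	0.00048609439691879792
138	0.00070752740988881853
139	0.00099986595328888203
140	0.0013718800745744174
141	0.0018275378204431342
142	0.0023637005444760643
143	0.002968208429211978
144	0.0036188633965925443
145	0.0042837670160180844
146	0.0049232892530975628
147	0.0054936466057552129
148	0.0059517124728719045
149	0.006260355889450943
150	0.0063934012279566847
151	0.0063392919674852399
152	0.0061027475593882262
153	0.0057040840191915016
154	0.0051763338553171218
155	0.0045607314574294903
156	0.0039014188691638557
157	0.0032403096638933373
158	0.0026129211781099702
159	0.0020457000638702044
160	0.0015550109997814622
161	0.0011476271899870047
162	0.00082232605289134643
163	0.00057208838087575368
164	0.00038641863478810774
165	0.00025341297839184384
166	0.00016135242675171176
167	9.974657836936598e-05
168	5.9868223202885323e-05
169	3.4887559350255526e-05
170	1.9738796262610098e-05
171	1.0842928587077273e-05
172	5.7829360195486144e-06
173	2.9945118384644801e-06
174	1.5054957651405149e-06
175	7.3486725997943603e-07
176	3.4826843690198439e-07
177	1.6024894956030633e-07
178	7.1589960529577421e-08
179	3.1051666384374312e-08
180	1.3076561388878847e-08
181	5.3466044975091858e-09
182	2.1224546459449229e-09
183	8.1804017883798037e-10
184	3.0611647818190515e-10
185	1.112178866361207e-10
186	3.9231817246399228e-11
187	1.3436249800707749e-11
188	4.4677984220817511e-12
189	1.4423973914431574e-12
190	4.5211835952237669e-13
191	1.3759264358538988e-13
192	4.0655016680583001e-14
193	1.1662963842403956e-14
194	3.2484753214692565e-15
195	8.7846825335531117e-16
196	2.3064732799126717e-16
197	5.8795845650145678e-17
198	1.4551933836400651e-17
199	3.4967987537105544e-18
200	8.1582389779299823e-19
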