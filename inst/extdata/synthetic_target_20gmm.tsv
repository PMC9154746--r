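# glycan_profile Ns=200 normalized=true
1	6.0838126686497701e-07
2	7.2067553785277971e-06
3	6.0489928293572873e-05
4	0.0003597541103983936
5	0.0015160311519551144
6	0.0045267999451279904
7	0.0095776952334160372
8	0.01435982869993363
9	0.015263632419672402
10	0.011540433307445627
11	0.0063701711460923439
12	0.0031273975217700847
13	0.0027819844953977393
14	0.0047727239051170633
15	0.008135753425459899
16	0.01147814372921039
17	0.013143943241495256
18	0.012197663983828202
19	0.00917229099272035
20	0.0055890655028570432
21	0.002761389063929926
22	0.0011192085291730932
23	0.00044639279667488225
24	0.00047955456797971039
25	0.0012793702299167256
26	0.0030880801856817512
27	0.0056659272575594792
28	0.0078029259591492327
29	0.0080606450161932342
30	0.0062596644472396289
31	0.0037289664581877857
32	0.0019996750161371665
33	0.0017745776157460297
34	0.0029331319569757021
35	0.0046947247226377326
36	0.0058086316375040746
37	0.0053875142344033816
38	0.0037329204863656884
39	0.0019321011116469888
40	0.00075585428942327238
41	0.00030565974755271315
42	0.00060883558090867658
43	0.002330794180661855
44	0.0063707442559247747
45	0.011591669025726078
46	0.014000819383118685
47	0.011224320715186295
48	0.0059725987231575243
49	0.0021094325137518107
50	0.00049463458705177913
51	7.814198584910783e-05
52	1.5789361874710736e-05
53	4.0231007377608048e-05
54	0.00015574003035998153
55	0.00047378736551304277
56	0.0011179184650689914
57	0.0020459511951195011
58	0.002907406565560411
59	0.0032272050401364314
60	0.0028865188911700469
61	0.0023827593414733855
62	0.0024960455773589615
63	0.0035913796938922731
64	0.0051248459067108404
65	0.0059314495946326991
66	0.0052769668230657875
67	0.0035681958219982522
68	0.0018299336320952979
69	0.00071774238398281934
70	0.00029605326193105053
71	0.00077360461011926859
72	0.0039560424806131455
73	0.013882110526424638
74	0.031589561763966524
75	0.046531526012703758
76	0.044364819748847734
77	0.027378945409247117
78	0.010936573203617853
79	0.002827721780815003
80	0.00047375407311973553
81	5.7832917034199382e-05
82	5.9721798227193761e-05
83	0.00032845753869733602
84	0.0013149333117817763
85	0.0036065920712636062
86	0.0067744700807904927
87	0.0087178223426134654
88	0.0077067546291311045
89	0.0047755332641550166
90	0.0023999456254808565
91	0.0017630854662358446
92	0.002421299572694558
93	0.0033396046629791086
94	0.0036185794895065779
95	0.0029817356581171637
96	0.0018675493159490617
97	0.00091794945139282811
98	0.00048408652776965659
99	0.00067413110009301841
100	0.0016190710834754901
101	0.0034010123584679226
102	0.0056232143800436117
103	0.0072547406642884081
104	0.0072985951024563253
105	0.0057255688996484264
106	0.003502689783819732
107	0.001674358982558052
108	0.00064881548872928389
109	0.00032556600357883591
110	0.0006100910185053252
111	0.0016599828040314098
112	0.0035577214234493097
113	0.0056738610663399861
114	0.0067093148770669348
115	0.0058812908828716082
116	0.0038217421295819146
117	0.0018415303460102418
118	0.00066293242958047457
119	0.00021060618156892492
120	0.00021613119685108998
121	0.00069302218879807836
122	0.0019792004867027592
123	0.0043281227023881184
124	0.0072010061057820587
125	0.0091130890811403405
126	0.008772318284665858
127	0.0064234764557158904
128	0.0035832913292596544
129	0.001567324194052125
130	0.00079791735864467015
131	0.0014253881148644522
132	0.0039214619148194903
133	0.0082492536752485236
134	0.01235165768109449
135	0.013108110771846784
136	0.0098833763446767413
137	0.0054064741975323165
138	0.0025271669218306682
139	0.0020080465166351252
140	0.0033790923601351849
141	0.006033569248679465
142	0.0091676472065633594
143	0.011576885123593188
144	0.01212935778923978
145	0.010550778482475992
146	0.0076580926316152619
147	0.0047828090291148302
148	0.002998094850820335
149	0.00277530555625209
150	0.003999339526033624
151	0.0059894301828710521
152	0.0076208795545797082
153	0.0078765593359953825
154	0.0065590680179024559
155	0.0043992963940756831
156	0.0024131720928223274
157	0.001278254143654004
158	0.0013562697067611208
159	0.0029735227716729197
160	0.006043077880497987
161	0.0091939673288582227
162	0.010220135368607412
163	0.0082795103684080822
164	0.0048872731891848303
165	0.0021080250076962845
166	0.00071122104326630357
167	0.00043048765728350867
168	0.0010298168520055373
169	0.0024449422335880437
170	0.004022531230061163
171	0.0044908243855132706
172	0.0033997579824502047
173	0.0017576836822822701
174	0.00071319861483116662
175	0.0007119714902471179
176	0.0022079839783990794
177	0.0060683077822975004
178	0.012174733237605644
179	0.017667406531463415
180	0.018537433827285361
181	0.014063197327608299
182	0.007713938617009075
183	0.0030594219857628946
184	0.00087897194906294974
185	0.00020126954773958078
186	0.00017328180423097114
187	0.00073139064900097498
188	0.0024069930413992378
189	0.0052665674313691129
190	0.0076325845924521589
191	0.0073260205530713439
192	0.0046571065601910978
193	0.0019607206641672026
194	0.00054672229431549746
195	0.00010096465121882948
196	1.2348762045096797e-05
197	1.0002970823999067e-06
198	5.3664376694177141e-08
199	1.9067540790271717e-09
200	4.4869867403589974e-11
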