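energy_keV,mu_per_cm
1,37434.1
2,5246.35
3,1662.05
4,735.269
5,390.579
6,232.934
7,150.467
8,103.047
9,73.7937
10,54.7392
11,41.7784
12,32.6454
13,26.0179
14,21.0877
15,17.3414
16,14.4463
17,12.1685
18,10.3509
19,8.88217
20,7.68192
21,6.72903
22,5.93078
23,5.25665
24,4.68313
25,4.19192
26,3.76857
27,3.40162
28,3.08186
29,2.80185
30,2.55552
31,2.36139
32,2.18749
33,2.03117
34,1.8902
35,1.76269
36,1.64702
37,1.5418
38,1.44585
39,1.35813
40,1.27776
41,1.21565
42,1.15794
43,1.10424
44,1.05418
45,1.00743
46,0.963725
47,0.922791
48,0.884404
49,0.848357
50,0.814464
51,0.788501
52,0.763847
53,0.740411
54,0.718113
55,0.696877
56,0.676634
57,0.657323
58,0.638884
59,0.621265
60,0.604416
61,0.592546
62,0.581096
63,0.570045
64,0.559374
65,0.549063
66,0.539095
67,0.529454
68,0.520125
69,0.511092
70,0.502343
71,0.493865
72,0.485646
73,0.477674
74,0.469938
75,0.462429
76,0.455138
77,0.448054
78,0.44117
79,0.434477
80,0.427968
81,0.423614
82,0.419358
83,0.415194
84,0.411122
85,0.407137
86,0.403236
87,0.399417
88,0.395677
89,0.392014
90,0.388426
91,0.384909
92,0.381462
93,0.378083
94,0.374769
95,0.371519
96,0.36833
97,0.365202
98,0.362132
99,0.359119
100,0.35616
101,0.354192
102,0.352253
103,0.350344
104,0.348464
105,0.346611
106,0.344786
107,0.342988
108,0.341215
109,0.339468
110,0.337745
111,0.336047
112,0.334373
113,0.332721
114,0.331093
115,0.329486
116,0.327901
117,0.326337
118,0.324793
119,0.32327
120,0.321767
121,0.320283
122,0.318818
123,0.317372
124,0.315944
125,0.314533
126,0.31314
127,0.311765
128,0.310406
129,0.309063
130,0.307737
131,0.306426
132,0.305131
133,0.303851
134,0.302586
135,0.301335
136,0.300099
137,0.298877
138,0.297669
139,0.296474
140,0.295292
141,0.294124
142,0.292969
143,0.291826
144,0.290695
145,0.289577
146,0.28847
147,0.287376
148,0.286293
149,0.285221
150,0.28416
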