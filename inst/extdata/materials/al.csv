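energy_keV,mu_per_cm
1,3198.31
2,6107.84
3,2126.81
4,972.99
5,521.987
6,311.195
7,199.586
8,135.841
9,96.3024
10,70.7948
11,53.4812
12,41.4005
13,32.7127
14,26.3034
15,21.4705
16,17.7907
17,14.9106
18,12.6236
19,10.784
20,9.28726
21,8.12086
22,7.14543
23,6.32303
24,5.62449
25,5.02709
26,4.51297
27,4.06797
28,3.68071
29,3.34204
30,3.04447
31,2.81575
32,2.61068
33,2.42618
34,2.25966
35,2.10891
36,1.97205
37,1.84747
38,1.73377
39,1.62975
40,1.53438
41,1.46233
42,1.39528
43,1.33277
44,1.2744
45,1.21982
46,1.1687
47,1.12076
48,1.07573
49,1.03338
50,0.993502
51,0.96359
52,0.935134
53,0.908037
54,0.88221
55,0.857571
56,0.834046
57,0.811566
58,0.790067
59,0.76949
60,0.749782
61,0.736138
62,0.722959
63,0.71022
64,0.697902
65,0.685983
66,0.674445
67,0.66327
68,0.652442
69,0.641945
70,0.631764
71,0.621886
72,0.612297
73,0.602985
74,0.593939
75,0.585147
76,0.576599
77,0.568285
78,0.560196
79,0.552323
80,0.544658
81,0.539554
82,0.534559
83,0.529671
84,0.524885
85,0.520198
86,0.515607
87,0.511108
88,0.5067
89,0.502379
90,0.498143
91,0.493988
92,0.489913
93,0.485915
94,0.481992
95,0.478142
96,0.474362
97,0.470651
98,0.467006
99,0.463426
100,0.45991
101,0.457519
102,0.455165
103,0.452845
104,0.450559
105,0.448307
106,0.446087
107,0.443899
108,0.441741
109,0.439614
110,0.437517
111,0.435448
112,0.433408
113,0.431395
114,0.429409
115,0.427449
116,0.425515
117,0.423607
118,0.421723
119,0.419863
120,0.418027
121,0.416214
122,0.414424
123,0.412656
124,0.41091
125,0.409185
126,0.407481
127,0.405798
128,0.404134
129,0.402491
130,0.400866
131,0.399261
132,0.397674
133,0.396105
134,0.394554
135,0.393021
136,0.391505
137,0.390006
138,0.388523
139,0.387057
140,0.385606
141,0.384172
142,0.382752
143,0.381348
144,0.379959
145,0.378584
146,0.377224
147,0.375878
148,0.374546
149,0.373227
150,0.371922
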