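energy_keV,mu_per_cm
1,26445.7
2,4442.92
3,1497.34
4,683.56
5,3081.2
6,1947.94
7,1296.77
8,911.564
9,663.093
10,498.814
11,382.732
12,300.516
13,240.576
14,195.794
15,161.63
16,134.57
17,113.292
18,96.3222
19,82.6158
20,71.4201
21,62.1203
22,54.3834
23,47.8924
24,42.405
25,37.7334
26,33.7304
27,30.2801
28,27.2895
29,24.6843
30,22.4038
31,20.4303
32,18.6853
33,17.1363
34,15.7564
35,14.5229
36,13.4168
37,12.4218
38,11.5243
39,10.7125
40,9.97628
41,9.33366
42,8.74646
43,8.20873
44,7.71532
45,7.26167
46,6.84381
47,6.45821
48,6.10179
49,5.77179
50,5.46578
51,5.19966
52,4.9513
53,4.71921
54,4.50202
55,4.29855
56,4.1077
57,3.92848
58,3.75999
59,3.60142
60,3.45205
61,3.328
62,3.21032
63,3.09858
64,2.99241
65,2.89143
66,2.79533
67,2.70379
68,2.61654
69,2.53332
70,2.45389
71,2.37803
72,2.30552
73,2.23617
74,2.16982
75,2.10628
76,2.04541
77,1.98706
78,1.9311
79,1.87739
80,1.82583
81,1.7858
82,1.74712
83,1.70974
84,1.67358
85,1.63861
86,1.60476
87,1.57199
88,1.54026
89,1.50951
90,1.47971
91,1.45082
92,1.42279
93,1.39561
94,1.36922
95,1.34361
96,1.31874
97,1.29457
98,1.27109
99,1.24827
100,1.22608
101,1.21111
102,1.19646
103,1.18212
104,1.1681
105,1.15437
106,1.14094
107,1.12778
108,1.1149
109,1.10228
110,1.08991
111,1.0778
112,1.06592
113,1.05428
114,1.04287
115,1.03168
116,1.02071
117,1.00994
118,0.999381
119,0.989018
120,0.978848
121,0.968865
122,0.959065
123,0.949443
124,0.939994
125,0.930715
126,0.921599
127,0.912644
128,0.903845
129,0.895198
130,0.8867
131,0.878347
132,0.870135
133,0.862061
134,0.854122
135,0.846314
136,0.838634
137,0.831079
138,0.823647
139,0.816334
140,0.809138
141,0.802055
142,0.795084
143,0.788222
144,0.781467
145,0.774815
146,0.768265
147,0.761815
148,0.755462
149,0.749204
150,0.743039
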