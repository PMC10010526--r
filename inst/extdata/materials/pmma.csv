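energy_keV,mu_per_cm
1,2243.91
2,333.673
3,109.435
4,49.6177
5,26.8647
6,16.2732
7,10.6513
8,7.37824
9,5.33714
10,3.99483
11,3.07389
12,2.41985
13,1.94183
14,1.58387
15,1.31019
16,1.13092
17,0.984928
18,0.864588
19,0.76432
20,0.679966
21,0.630044
22,0.585862
23,0.546542
24,0.511371
25,0.479764
26,0.451239
27,0.425393
28,0.401888
29,0.380441
30,0.360808
31,0.35048
32,0.340761
33,0.331599
34,0.322946
35,0.31476
36,0.307004
37,0.299643
38,0.292648
39,0.285992
40,0.27965
41,0.27581
42,0.272114
43,0.268553
44,0.265118
45,0.261803
46,0.258601
47,0.255506
48,0.252512
49,0.249614
50,0.246806
51,0.244802
52,0.242852
53,0.240955
54,0.239107
55,0.237308
56,0.235554
57,0.233843
58,0.232174
59,0.230546
60,0.228956
61,0.22772
62,0.22651
63,0.225327
64,0.224167
65,0.223032
66,0.221919
67,0.220829
68,0.21976
69,0.218712
70,0.217684
71,0.216675
72,0.215685
73,0.214712
74,0.213758
75,0.21282
76,0.211899
77,0.210994
78,0.210104
79,0.209229
80,0.208369
81,0.207618
82,0.206878
83,0.206151
84,0.205434
85,0.204728
86,0.204033
87,0.203348
88,0.202674
89,0.202009
90,0.201354
91,0.200708
92,0.200071
93,0.199443
94,0.198824
95,0.198213
96,0.197611
97,0.197016
98,0.196429
99,0.19585
100,0.195279
101,0.194707
102,0.194142
103,0.193584
104,0.193033
105,0.192488
106,0.191951
107,0.19142
108,0.190895
109,0.190377
110,0.189865
111,0.189359
112,0.188858
113,0.188364
114,0.187875
115,0.187391
116,0.186913
117,0.186441
118,0.185973
119,0.185511
120,0.185053
121,0.184601
122,0.184153
123,0.18371
124,0.183272
125,0.182838
126,0.182409
127,0.181984
128,0.181563
129,0.181147
130,0.180735
131,0.180327
132,0.179923
133,0.179523
134,0.179126
135,0.178734
136,0.178345
137,0.17796
138,0.177579
139,0.177201
140,0.176827
141,0.176456
142,0.176088
143,0.175724
144,0.175363
145,0.175006
146,0.174651
147,0.1743
148,0.173951
149,0.173606
150,0.173264
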