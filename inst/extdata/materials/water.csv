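energy_keV,mu_per_cm
1,4078
2,617.3
3,192.9
4,82.78
5,42.58
6,24.64
7,15.4967
8,10.37
9,7.29733
10,5.329
11,4.05857
12,3.16519
13,2.5181
14,2.03756
15,1.673
16,1.4216
17,1.21997
18,1.05613
19,0.921456
20,0.8096
21,0.738133
22,0.675875
23,0.621297
24,0.573177
25,0.530527
26,0.492542
27,0.458561
28,0.428036
29,0.40051
30,0.3756
31,0.36147
32,0.348296
33,0.335985
34,0.324458
35,0.313644
36,0.30348
37,0.29391
38,0.284886
39,0.276362
40,0.2683
41,0.26337
42,0.258646
43,0.254115
44,0.249765
45,0.245585
46,0.241564
47,0.237694
48,0.233965
49,0.230369
50,0.2269
51,0.224519
52,0.222209
53,0.219966
54,0.217786
55,0.215668
56,0.213608
57,0.211603
58,0.209652
59,0.207752
60,0.2059
61,0.204555
62,0.20324
63,0.201954
64,0.200697
65,0.199467
66,0.198263
67,0.197084
68,0.195929
69,0.194798
70,0.19369
71,0.192603
72,0.191538
73,0.190493
74,0.189468
75,0.188462
76,0.187475
77,0.186506
78,0.185554
79,0.184619
80,0.1837
81,0.182951
82,0.182214
83,0.181489
84,0.180776
85,0.180073
86,0.179382
87,0.178701
88,0.17803
89,0.17737
90,0.176719
91,0.176078
92,0.175446
93,0.174824
94,0.17421
95,0.173604
96,0.173007
97,0.172419
98,0.171838
99,0.171265
100,0.1707
101,0.170173
102,0.169653
103,0.16914
104,0.168633
105,0.168133
106,0.167638
107,0.16715
108,0.166668
109,0.166191
110,0.16572
111,0.165255
112,0.164796
113,0.164341
114,0.163892
115,0.163448
116,0.163009
117,0.162575
118,0.162146
119,0.161721
120,0.161302
121,0.160886
122,0.160475
123,0.160069
124,0.159667
125,0.159269
126,0.158875
127,0.158486
128,0.1581
129,0.157718
130,0.157341
131,0.156967
132,0.156596
133,0.156229
134,0.155866
135,0.155507
136,0.155151
137,0.154798
138,0.154449
139,0.154103
140,0.15376
141,0.153421
142,0.153084
143,0.152751
144,0.15242
145,0.152093
146,0.151769
147,0.151447
148,0.151129
149,0.150813
150,0.1505
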