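energy_keV,mu_per_cm
1,3986.36
2,554.606
3,174.948
4,77.1599
5,40.8912
6,24.3398
7,15.697
8,10.7349
9,7.6779
10,5.68902
11,4.33763
12,3.38629
13,2.69654
14,2.18386
15,1.79458
16,1.52542
17,1.30948
18,1.13395
19,0.989631
20,0.86973
21,0.792363
22,0.725013
23,0.666014
24,0.61403
25,0.567985
26,0.527002
27,0.49036
28,0.457463
29,0.427815
30,0.400998
31,0.385859
32,0.371746
33,0.35856
34,0.346215
35,0.334634
36,0.323751
37,0.313506
38,0.303846
39,0.294723
40,0.286094
41,0.280584
42,0.275309
43,0.270254
44,0.265404
45,0.260748
46,0.256273
47,0.251969
48,0.247825
49,0.243833
50,0.239984
51,0.237385
52,0.234863
53,0.232416
54,0.230039
55,0.227729
56,0.225483
57,0.223299
58,0.221173
59,0.219104
60,0.217088
61,0.215641
62,0.214227
63,0.212845
64,0.211493
65,0.210171
66,0.208877
67,0.20761
68,0.20637
69,0.205154
70,0.203964
71,0.202797
72,0.201652
73,0.20053
74,0.19943
75,0.19835
76,0.19729
77,0.196249
78,0.195227
79,0.194224
80,0.193238
81,0.192444
82,0.191662
83,0.190894
84,0.190137
85,0.189393
86,0.18866
87,0.187938
88,0.187227
89,0.186527
90,0.185837
91,0.185158
92,0.184488
93,0.183828
94,0.183177
95,0.182536
96,0.181903
97,0.181279
98,0.180664
99,0.180057
100,0.179458
101,0.178902
102,0.178354
103,0.177812
104,0.177277
105,0.176749
106,0.176228
107,0.175713
108,0.175204
109,0.174702
110,0.174205
111,0.173714
112,0.173229
113,0.17275
114,0.172276
115,0.171808
116,0.171345
117,0.170887
118,0.170434
119,0.169987
120,0.169544
121,0.169106
122,0.168672
123,0.168244
124,0.16782
125,0.1674
126,0.166985
127,0.166574
128,0.166167
129,0.165765
130,0.165366
131,0.164972
132,0.164581
133,0.164194
134,0.163811
135,0.163432
136,0.163057
137,0.162685
138,0.162316
139,0.161951
140,0.16159
141,0.161232
142,0.160877
143,0.160526
144,0.160177
145,0.159832
146,0.15949
147,0.159151
148,0.158815
149,0.158482
150,0.158152
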