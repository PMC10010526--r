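energy_keV,mu_per_cm
1,4.34523
2,0.63612
3,0.195812
4,0.0938454
5,0.0485254
6,0.028209
7,0.0178075
8,0.0119548
9,0.00843147
10,0.0061696
11,0.00470331
12,0.00367124
13,0.00292306
14,0.00236702
15,0.00194487
16,0.00165112
17,0.00141573
18,0.00122462
19,0.00106765
20,0.00093737
21,0.000852585
22,0.000778897
23,0.000714443
24,0.000657737
25,0.00060758
26,0.000562996
27,0.000523187
28,0.000487491
29,0.000455359
30,0.000426329
31,0.000409503
32,0.000393844
33,0.000379239
34,0.000365587
35,0.000352802
36,0.000340805
37,0.000329529
38,0.000318911
39,0.000308899
40,0.000299442
41,0.000293605
42,0.000288018
43,0.000282665
44,0.000277532
45,0.000272603
46,0.000267868
47,0.000263314
48,0.000258932
49,0.00025471
50,0.00025064
51,0.000247831
52,0.000245108
53,0.000242465
54,0.000239899
55,0.000237407
56,0.000234985
57,0.00023263
58,0.000230339
59,0.000228109
60,0.000225937
61,0.000224377
62,0.000222853
63,0.000221364
64,0.000219907
65,0.000218483
66,0.000217089
67,0.000215725
68,0.000214389
69,0.000213082
70,0.0002118
71,0.000210545
72,0.000209314
73,0.000208107
74,0.000206924
75,0.000205763
76,0.000204624
77,0.000203505
78,0.000202408
79,0.00020133
80,0.000200271
81,0.00019943
82,0.000198603
83,0.000197789
84,0.000196988
85,0.0001962
86,0.000195424
87,0.00019466
88,0.000193908
89,0.000193167
90,0.000192438
91,0.000191719
92,0.00019101
93,0.000190312
94,0.000189624
95,0.000188945
96,0.000188276
97,0.000187616
98,0.000186966
99,0.000186324
100,0.00018569
101,0.000185109
102,0.000184534
103,0.000183967
104,0.000183407
105,0.000182855
106,0.000182309
107,0.00018177
108,0.000181237
109,0.000180711
110,0.000180191
111,0.000179678
112,0.00017917
113,0.000178668
114,0.000178173
115,0.000177682
116,0.000177198
117,0.000176719
118,0.000176245
119,0.000175776
120,0.000175313
121,0.000174855
122,0.000174401
123,0.000173953
124,0.000173509
125,0.00017307
126,0.000172636
127,0.000172206
128,0.00017178
129,0.000171359
130,0.000170942
131,0.00017053
132,0.000170121
133,0.000169717
134,0.000169316
135,0.000168919
136,0.000168527
137,0.000168138
138,0.000167752
139,0.000167371
140,0.000166993
141,0.000166618
142,0.000166247
143,0.00016588
144,0.000165516
145,0.000165155
146,0.000164797
147,0.000164443
148,0.000164091
149,0.000163743
150,0.000163398
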