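energy_keV,mu_per_cm
1,94707.2
2,19299.8
3,6709.25
4,3111.81
5,1701.5
6,1057.28
7,685.402
8,470.848
9,2480.75
10,1934.46
11,1504.25
12,1195.61
13,967.942
14,795.994
15,663.488
16,556.407
17,471.614
18,403.541
19,348.216
20,302.758
21,264.281
22,232.157
23,205.116
24,182.183
25,162.599
26,145.769
27,131.221
28,118.578
29,107.534
30,97.8432
31,89.2231
32,81.6011
33,74.8355
34,68.8085
35,63.4211
36,58.5898
37,54.2443
38,50.3244
39,46.7788
40,43.5635
41,40.6707
42,38.0328
43,35.6222
44,33.4147
45,31.3891
46,29.5268
47,27.8116
48,26.229
49,24.7664
50,23.4125
51,22.1873
52,21.0481
53,19.9875
54,18.9987
55,18.0757
56,17.2129
57,16.4055
58,15.649
59,14.9395
60,14.2733
61,13.6822
62,13.1246
63,12.5981
64,12.1005
65,11.6299
66,11.1843
67,10.7621
68,10.3618
69,9.98185
70,9.62103
71,9.27809
72,8.95192
73,8.64148
74,8.34581
75,8.06403
76,7.7953
77,7.53887
78,7.29403
79,7.0601
80,6.83648
81,6.64529
82,6.46169
83,6.2853
84,6.11575
85,5.9527
86,5.79583
87,5.64484
88,5.49944
89,5.35936
90,5.22436
91,5.0942
92,4.96864
93,4.84749
94,4.73055
95,4.61761
96,4.50852
97,4.40309
98,4.30117
99,4.20261
100,4.10726
101,4.03469
102,3.9641
103,3.89542
104,3.82857
105,3.76349
106,3.70012
107,3.63839
108,3.57826
109,3.51966
110,3.46254
111,3.40685
112,3.35255
113,3.29958
114,3.24791
115,3.19748
116,3.14827
117,3.10023
118,3.05331
119,3.0075
120,2.96275
121,2.91902
122,2.87629
123,2.83453
124,2.79371
125,2.7538
126,2.71477
127,2.67659
128,2.63924
129,2.6027
130,2.56694
131,2.53194
132,2.49768
133,2.46413
134,2.43129
135,2.39912
136,2.3676
137,2.33673
138,2.30648
139,2.27684
140,2.24778
141,2.2193
142,2.19138
143,2.164
144,2.13715
145,2.11082
146,2.08499
147,2.05965
148,2.03478
149,2.01038
150,1.98643
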