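molecule_id,CS
1,62.419
54,14.237
102,63.460
154,55.058
2,70.497
55,93.809
103,68.261
155,30.561
3,74.645
56,56.244
104,39.281
158,40.348
4,76.761
57,53.336
105,75.164
160,34.447
5,59.291
58,86.330
106,44.280
161,37.484
6,79.569
59,93.996
107,52.755
162,37.567
9,80.267
60,93.801
108,48.741
163,66.179
10,34.540
61,78.122
109,86.599
164,17.431
11,81.129
62,26.500
110,39.848
166,26.236
12,88.565
63,81.574
111,78.467
167,56.086
13,90.223
64,75.959
112,27.825
168,28.220
14,43.984
65,46.755
113,25.711
170,29.298
15,65.275
66,94.067
114,39.093
171,39.336
16,62.587
67,89.974
115,31.501
172,37.749
18,81.201
68,59.719
116,61.154
173,18.817
19,55.063
69,29.886
117,70.919
174,22.688
20,83.315
70,72.018
118,52.467
175,13.265
21,60.642
71,55.668
119,29.131
176,45.561
22,88.196
72,62.223
120,0.240
177,65.328
23,36.415
73,25.795
121,6.780
179,29.598
24,43.771
74,44.307
122,66.126
180,30.582
25,90.695
75,46.193
123,62.548
181,47.201
26,88.768
76,63.293
124,46.521
182,38.525
27,50.537
78,85.128
125,13.029
184,36.552
29,64.633
79,75.962
126,73.484
185,13.124
31,62.105
80,82.678
128,29.168
186,21.388
33,70.747
81,94.955
131,30.241
187,11.322
34,86.001
82,43.790
132,52.710
188,16.529
35,83.023
83,66.221
133,73.068
189,36.085
36,70.563
84,29.600
136,48.766
190,37.782
37,89.614
86,47.469
138,42.118
191,34.827
38,79.796
87,67.402
139,46.441
192,29.639
39,93.673
88,47.519
140,44.752
193,13.686
40,65.097
89,36.692
141,52.452
195,35.669
41,64.348
90,70.135
142,36.330
196,46.589
42,55.049
91,67.806
143,15.026
197,13.816
43,92.168
92,69.475
144,57.608
198,5.979
44,93.996
93,25.175
145,21.100
200,20.186
45,43.310
94,63.460
146,31.664
201,17.126
48,90.877
95,38.738
147,62.187
202,21.403
49,72.572
96,37.174
148,16.047
203,16.630
50,56.752
97,70.135
149,4.596
207,30.333
51,48.494
98,45.294
150,42.800
52,58.896
99,64.597
151,10.233
53,61.615
101,54.593
152,23.944
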