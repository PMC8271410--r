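molecule_id,PS,MS
1,50.733,55.710
54,44.215,38.509
102,49.677,56.691
154,28.227,58.385
2,57.837,54.414
55,59.243,63.288
103,48.879,59.590
155,45.577,49.031
3,54.702,53.951
56,52.388,52.759
104,51.399,43.820
158,33.236,55.042
4,53.765,58.411
57,46.600,56.159
105,22.051,66.738
160,49.039,47.847
5,51.594,54.430
58,52.568,66.686
106,37.133,55.909
161,43.484,53.569
6,54.788,58.776
59,60.472,60.682
107,40.979,58.222
162,43.448,53.694
9,56.667,58.159
60,62.142,60.081
108,50.356,52.020
163,52.614,55.499
10,48.301,48.648
61,60.028,55.127
109,57.796,60.055
164,43.981,43.946
11,56.974,58.361
62,47.218,45.482
110,50.426,48.015
166,44.549,48.599
12,59.214,59.652
63,53.948,60.093
111,60.748,54.667
167,36.432,59.307
13,57.526,62.455
64,55.251,57.275
112,42.758,50.425
168,45.575,48.689
14,46.754,53.730
65,50.753,49.440
113,41.305,50.123
170,44.321,49.409
15,60.261,48.748
66,62.080,60.168
114,45.632,52.818
171,44.514,53.524
16,55.174,53.059
67,55.945,63.837
115,44.264,50.525
172,28.530,54.541
18,51.739,61.670
68,49.737,55.682
116,60.087,47.239
173,39.364,48.431
19,50.613,53.869
69,43.235,51.439
117,57.489,54.592
174,46.630,43.739
20,61.828,56.043
70,53.591,57.129
118,46.867,55.849
175,29.743,47.470
21,59.743,47.605
71,48.967,55.600
119,41.126,51.845
176,52.210,47.876
22,56.985,61.494
72,34.005,61.398
120,23.833,32.945
177,52.552,55.468
23,46.574,51.513
73,48.682,37.079
121,37.530,39.004
179,48.790,44.680
24,50.741,48.690
74,47.394,53.408
122,50.160,57.683
180,43.234,51.712
25,57.937,61.921
75,42.093,56.075
123,49.449,57.237
181,43.164,56.096
26,55.000,66.484
76,57.124,51.931
124,49.217,52.803
182,47.599,50.822
27,48.062,54.728
78,57.964,58.741
125,35.000,45.774
184,47.169,50.452
29,55.790,53.374
79,52.080,58.986
126,59.742,54.379
185,34.935,46.142
31,55.890,52.077
80,55.455,59.350
128,44.885,49.017
186,46.193,42.368
33,57.809,54.456
81,63.311,60.652
131,37.731,52.188
187,28.077,46.347
34,54.998,62.107
82,40.683,55.810
132,48.683,54.837
188,42.491,45.731
35,59.593,57.332
83,53.855,54.972
133,52.406,57.826
189,43.676,53.130
36,52.978,56.362
84,47.792,46.413
136,55.272,43.873
190,45.756,52.131
37,63.410,58.137
86,47.246,54.512
138,37.551,55.567
191,42.498,53.366
38,55.095,58.726
87,44.090,63.495
139,34.033,56.214
192,49.392,39.556
39,58.382,64.565
88,31.567,56.544
140,49.381,51.854
193,40.695,44.963
40,53.988,54.565
89,50.567,45.006
141,54.419,48.726
195,48.284,48.900
41,59.806,48.917
90,51.033,57.709
142,49.549,47.546
196,51.013,49.047
42,50.645,53.764
91,58.794,52.697
143,44.001,39.951
197,31.670,47.313
43,58.173,63.262
92,51.110,57.428
144,30.790,59.308
198,30.236,41.261
44,60.472,60.682
93,38.732,50.418
145,44.858,45.424
200,45.785,40.797
45,50.950,48.487
94,49.677,56.691
146,47.708,48.258
201,45.450,38.554
48,59.166,61.223
95,51.612,39.231
147,51.697,54.749
202,47.098,34.293
49,50.075,59.706
96,50.716,44.696
148,43.867,43.268
203,31.091,48.457
50,49.330,55.678
97,51.033,57.709
149,26.750,40.848
207,45.193,49.078
51,49.461,52.917
98,49.576,51.478
150,49.542,50.205
52,60.068,41.767
99,48.567,58.439
151,42.035,39.152
53,48.198,57.865
101,54.120,49.688
152,47.398,40.260
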