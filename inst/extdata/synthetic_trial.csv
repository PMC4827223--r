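id,arm,x,y
1,1,1.216266,1
2,1,-0.493843,1
3,0,-0.227785,0
4,0,-1.111649,1
5,1,0.995833,0
6,0,0.561829,0
7,0,-1.564279,1
8,1,1.481077,1
9,0,-1.169205,0
10,1,-1.052014,1
11,0,-1.471846,0
12,1,-1.193437,0
13,0,-0.347979,0
14,1,0.532823,1
15,0,-0.710989,1
16,0,-0.198989,1
17,1,-0.281373,1
18,0,1.170926,1
19,0,2.288733,1
20,0,-1.068857,0
21,0,1.906204,0
22,0,2.131798,1
23,0,0.231456,0
24,0,0.896946,1
25,0,-1.738793,1
26,0,0.468848,0
27,0,-0.544148,1
28,0,-0.165414,1
29,0,0.552167,0
30,1,1.03333,1
31,1,-0.046179,0
32,0,2.638707,1
33,1,0.589006,0
34,0,-0.202377,1
35,1,0.44156,0
36,0,-0.100258,1
37,0,-1.093404,1
38,0,0.503247,1
39,1,0.94924,1
40,0,0.382802,1
41,0,0.371578,1
42,1,0.157216,1
43,0,0.84794,1
44,0,-1.283393,0
45,0,1.158279,1
46,0,-0.909106,1
47,1,0.334991,1
48,0,0.775854,1
49,1,0.23714,1
50,0,-1.55987,0
51,1,0.024327,1
52,1,0.334635,1
53,1,0.989411,1
54,1,0.500375,0
55,1,0.576908,1
56,1,1.142691,0
57,1,-0.707448,1
58,0,-0.61856,0
59,1,-0.008314,1
60,0,0.33892,1
61,0,1.405406,0
62,1,-0.86527,0
63,1,-0.873954,1
64,0,0.774318,0
65,0,-0.40189,0
66,0,-0.215138,0
67,1,0.605256,0
68,0,-0.614568,1
69,1,-0.724423,0
70,1,-0.256943,1
71,1,-0.392073,1
72,0,-0.686702,1
73,1,0.87584,1
74,1,-0.481058,1
75,0,0.068358,0
76,1,0.137025,1
77,1,-1.858769,1
78,1,0.346277,1
79,0,1.501634,1
80,1,-0.013738,1
81,0,-0.775245,1
82,1,1.311158,0
83,1,0.260525,1
84,1,1.014017,1
85,0,0.215594,1
86,1,0.613405,1
87,1,1.445988,1
88,1,0.658086,1
89,0,0.375234,0
90,0,-0.674688,0
91,1,0.580481,1
92,1,-0.414229,0
93,1,2.180504,1
94,0,0.342858,0
95,0,-0.798025,1
96,0,1.641036,1
97,1,-0.460005,1
98,0,-1.586471,0
99,1,-1.044916,1
100,0,0.041654,0
101,0,-0.432026,1
102,1,0.458591,1
103,0,-0.229352,0
104,0,-1.856962,0
105,0,-0.289674,1
106,0,1.767141,1
107,1,-0.442683,0
108,1,-0.588864,1
109,0,-0.120588,0
110,1,1.653061,1
111,0,-0.871355,0
112,1,0.780668,1
113,0,-0.613878,0
114,0,-0.327591,0
115,0,-0.355216,0
116,0,0.780934,1
117,1,0.60867,0
118,0,1.076179,1
119,0,1.065558,0
120,1,2.161646,1
121,0,0.070456,1
122,0,-2.535225,0
123,1,-0.541334,0
124,1,-0.77594,1
125,0,-0.295955,0
126,0,1.151373,1
127,0,-0.568888,0
128,0,-0.805786,0
129,0,0.492594,1
130,0,0.700758,0
131,0,-0.243125,1
132,1,0.412481,1
133,0,0.498165,0
134,0,0.367679,0
135,1,-0.570603,1
136,0,0.738817,1
137,0,-2.268291,0
138,1,0.614041,0
139,1,0.403636,1
140,0,2.051579,1
141,1,0.263245,1
142,0,0.110421,0
143,1,1.195764,1
144,1,0.73331,0
145,1,-0.004512,1
146,0,-0.021215,1
147,0,0.138502,0
148,1,-1.070127,1
149,1,1.236062,1
150,0,-0.53981,1
151,0,-0.296229,0
152,0,0.688219,0
153,1,-0.399007,1
154,1,-0.103485,1
155,1,1.529534,0
156,1,-0.634636,1
157,0,-0.226855,0
158,1,1.501084,0
159,1,-0.342463,1
160,0,-0.553728,0
161,0,0.257627,1
162,1,0.613122,1
163,1,-0.652287,1
164,0,-0.138281,1
165,0,-0.123638,0
166,0,-0.964705,0
167,0,0.019043,1
168,0,1.691692,1
169,0,0.885809,0
170,0,-0.72993,0
171,1,0.351885,0
172,1,-0.247331,1
173,0,-0.163592,1
174,1,0.872361,0
175,0,0.605938,1
176,1,0.927241,1
177,1,0.458044,0
178,1,-0.801114,1
179,1,-0.497123,1
180,1,-1.212968,1
181,0,0.619713,0
182,0,1.359663,1
183,1,-1.621065,1
184,1,0.079559,0
185,0,0.512593,0
186,0,-0.219102,1
187,1,-0.825939,1
188,0,-1.013578,0
189,0,1.282066,1
190,0,-0.212144,0
191,0,1.184877,0
192,0,-0.650612,0
193,0,1.287367,1
194,1,0.538933,0
195,0,0.025541,0
196,0,1.163948,1
197,0,-0.367626,1
198,1,-0.36337,1
199,1,-0.006753,0
200,0,-0.100472,0
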