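channel,x,y,z
1,0.062663,0.059775,-0.027906
2,0.057295,0.07264,0.003329
3,0.041837,0.082656,0.033215
4,0.031061,0.077367,0.054022
5,0.016017,0.061569,0.073763
6,0.0,0.041216,0.085439
7,-0.01325,0.016878,0.091385
8,0.045711,0.086604,-0.014668
9,0.029183,0.096196,0.011783
10,0.019823,0.094291,0.034507
11,0.0,0.086212,0.054619
12,-0.016017,0.061569,0.073763
13,-0.026373,0.035235,0.08238
14,0.013755,0.10263,-0.010255
15,0.0,0.09839,0.014436
16,0.0,0.098272,0.033623
17,0.0,0.100379,-0.023944
18,-0.019823,0.094291,0.034507
19,-0.031061,0.077367,0.054022
20,-0.041422,0.055452,0.064343
21,-0.013755,0.10263,-0.010255
22,-0.029183,0.096196,0.011783
23,-0.041837,0.082656,0.033215
24,-0.048282,0.065191,0.047264
25,-0.045711,0.086604,-0.014668
26,-0.057295,0.07264,0.003329
27,-0.061525,0.059044,0.030712
28,-0.060054,0.045017,0.050103
29,-0.05156,0.02921,0.068185
30,-0.040011,0.010398,0.082587
31,-0.021169,-0.00741,0.092732
32,-0.062663,0.059775,-0.027906
33,-0.069283,0.044686,-0.003864
34,-0.073883,0.032139,0.026311
35,-0.06945,0.016133,0.05134
36,-0.059323,0.003085,0.069113
37,-0.042333,-0.016447,0.084063
38,-0.070925,0.039102,-0.036305
39,-0.077864,0.009204,-0.00956
40,-0.080033,0.000348,0.023209
41,-0.074761,-0.008672,0.049805
42,-0.064486,-0.025324,0.065001
43,-0.070581,0.026172,-0.056881
44,-0.074065,0.013842,-0.038494
45,-0.079087,-0.020206,-0.006812
46,-0.079173,-0.024887,0.025826
47,-0.072945,-0.032609,0.04524
48,-0.064254,0.024112,-0.085906
49,-0.06819,0.004511,-0.065711
50,-0.073434,-0.043563,-0.002514
51,-0.071004,-0.05053,0.029774
52,-0.063135,-0.048666,0.053652
53,-0.045403,-0.043709,0.075604
54,-0.024586,-0.036973,0.088831
55,0.0,-0.023152,0.09519
56,-0.066857,-0.026614,-0.061036
57,-0.071247,-0.040488,-0.032385
58,-0.065338,-0.062318,0.000561
59,-0.056349,-0.069703,0.032313
60,-0.044574,-0.065629,0.058095
61,-0.025388,-0.059344,0.076415
62,0.0,-0.072289,0.069999
63,-0.057743,-0.046581,-0.060778
64,-0.05851,-0.063558,-0.031308
65,-0.050295,-0.078827,0.001409
66,-0.039067,-0.082995,0.033888
67,-0.019972,-0.079627,0.05656
68,-0.04098,-0.069304,-0.056951
69,-0.038207,-0.082318,-0.030511
70,-0.029654,-0.093199,0.002592
71,-0.015212,-0.091353,0.035483
72,0.0,-0.084775,0.050753
73,-0.020892,-0.081172,-0.055616
74,-0.012188,-0.091545,-0.028506
75,0.0,-0.097407,0.005283
76,0.015212,-0.091353,0.035483
77,0.019972,-0.079627,0.05656
78,0.025388,-0.059344,0.076415
79,0.024586,-0.036973,0.088831
80,0.021169,-0.00741,0.092732
81,0.0,-0.085089,-0.053544
82,0.012188,-0.091545,-0.028506
83,0.029654,-0.093199,0.002592
84,0.039067,-0.082995,0.033888
85,0.044574,-0.065629,0.058095
86,0.045403,-0.043709,0.075604
87,0.042333,-0.016447,0.084063
88,0.020892,-0.081172,-0.055616
89,0.038207,-0.082318,-0.030511
90,0.050295,-0.078827,0.001409
91,0.056349,-0.069703,0.032313
92,0.063135,-0.048666,0.053652
93,0.064486,-0.025324,0.065001
94,0.04098,-0.069304,-0.056951
95,0.05851,-0.063558,-0.031308
96,0.065338,-0.062318,0.000561
97,0.071004,-0.05053,0.029774
98,0.072945,-0.032609,0.04524
99,0.057743,-0.046581,-0.060778
100,0.071247,-0.040488,-0.032385
101,0.073434,-0.043563,-0.002514
102,0.079173,-0.024887,0.025826
103,0.074761,-0.008672,0.049805
104,0.059323,0.003085,0.069113
105,0.040011,0.010398,0.082587
106,0.01325,0.016878,0.091385
107,0.066857,-0.026614,-0.061036
108,0.079087,-0.020206,-0.006812
109,0.080033,0.000348,0.023209
110,0.06945,0.016133,0.05134
111,0.05156,0.02921,0.068185
112,0.026373,0.035235,0.08238
113,0.06819,0.004511,-0.065711
114,0.074065,0.013842,-0.038494
115,0.077864,0.009204,-0.00956
116,0.073883,0.032139,0.026311
117,0.060054,0.045017,0.050103
118,0.041422,0.055452,0.064343
119,0.064254,0.024112,-0.085906
120,0.070581,0.026172,-0.056881
121,0.070925,0.039102,-0.036305
122,0.069283,0.044686,-0.003864
123,0.061525,0.059044,0.030712
124,0.048282,0.065191,0.047264
125,0.066245,0.04898,-0.047738
126,0.040531,0.071991,-0.070703
127,-0.040531,0.071991,-0.070703
128,-0.066245,0.04898,-0.047738
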