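cluster,episode,L1,R1,o2,L2,R2,female
1,1,1.34,1.974,1,1.16,1.852,0
1,2,7.643,9.166,0,,,0
2,1,4.754,5.446,1,1.92,2.511,1
2,2,3.21,4.21,0,,,1
3,1,1.066,1.797,1,5.982,7.333,0
3,2,0.564,1.696,0,,,0
4,1,2.223,3.923,1,2.227,3.402,0
4,2,3.521,4.777,0,,,0
5,1,4.147,5.763,1,2.171,2.612,0
5,2,1.757,2.344,0,,,0
6,1,5.093,6.334,1,1.104,1.978,0
7,1,2.937,4.132,1,4.077,5.295,0
7,2,1.642,2.941,0,,,0
8,1,2.303,3.617,1,8.324,9.579,0
9,1,5.368,5.998,1,1.69,2.962,0
9,2,2.28,3.957,0,,,0
10,1,3.603,5.248,1,3.672,4.139,0
10,2,3.475,4.543,0,,,0
11,1,0.994,2.534,1,3.01,3.718,0
11,2,0.711,1.494,0,,,0
12,1,2.223,2.786,1,2.514,3.007,0
12,2,0,0.866,0,,,0
13,1,1.103,2.589,1,4.302,5.196,1
13,2,0.643,1.751,0,,,1
14,1,2.534,3.618,1,5.586,6.935,1
14,2,1.822,2.912,0,,,1
15,1,2.659,3.962,1,4.581,5.812,0
15,2,7.096,8.326,0,,,0
16,1,0.66,1.778,1,0.97,1.526,0
16,2,3.208,4.815,1,0.412,1.524,0
16,3,0,1.169,0,,,0
17,1,1.44,2.793,1,0,0.671,0
17,2,5.47,6.541,0,,,0
18,1,3.785,5.368,1,2.942,3.786,1
18,2,3.549,5.21,0,,,1
19,1,4.907,5.707,1,0.019,0.453,0
19,2,1.32,2.119,0,,,0
20,1,0.807,2.345,1,5.309,6.436,0
20,2,3.599,5.043,0,,,0
21,1,2.68,3.434,1,2.027,3.4,0
21,2,3.122,3.656,0,,,0
22,1,2.361,3.412,1,3.362,3.875,0
22,2,0.931,2.269,0,,,0
23,1,2.212,3.882,1,2.81,4.139,0
23,2,3.077,3.646,0,,,0
24,1,0.064,1.426,1,4.978,5.836,0
24,2,3.918,5.215,0,,,0
25,1,3.611,4.804,1,5.386,6.512,0
25,2,1.856,2.733,0,,,0
26,1,0.308,1.508,1,2.379,3.316,0
26,2,0.949,2.03,0,,,0
27,1,1.657,3.066,1,3.851,4.974,0
27,2,2.241,3.866,0,,,0
28,1,1.74,3.164,1,2.393,3.586,0
28,2,2.181,2.741,0,,,0
29,1,0.464,1.712,1,4.868,5.736,0
30,1,3.726,5.161,1,6.175,7.442,0
30,2,0.052,0.553,0,,,0
31,1,3.957,4.904,1,2.23,3.19,0
31,2,5.76,6.714,0,,,0
32,1,1.426,2.326,1,2.035,2.981,0
32,2,2.549,3.878,0,,,0
33,1,1.862,2.723,1,2.139,2.928,0
33,2,1.17,2.365,0,,,0
34,1,2.627,4.26,1,1.063,2.259,0
34,2,2.735,4.141,0,,,0
35,1,3.495,4.866,1,1.739,3.054,0
35,2,2.702,4.344,0,,,0
36,1,2.708,3.876,1,1.323,2.481,0
36,2,0.155,0.913,0,,,0
37,1,1.577,2.598,1,4.414,5.432,0
37,2,2.748,4.304,0,,,0
38,1,1.384,2.168,1,5.128,5.991,0
38,2,0.946,2.238,0,,,0
39,1,0.067,1.702,1,6.742,8.039,0
39,2,2.903,3.461,1,2.668,3.603,0
39,3,0.676,1.214,0,,,0
40,1,0.66,1.588,1,4.371,5.088,0
40,2,2.975,4.122,0,,,0
41,1,2.035,3.458,1,2.508,3.69,1
41,2,2.791,4.044,0,,,1
42,1,1.169,1.785,1,5.376,6.654,0
42,2,4.16,5.183,0,,,0
43,1,1.902,2.8,1,2.597,3.988,0
44,1,2.9,4.336,1,1.22,2.524,0
44,2,2.886,4.346,0,,,0
45,1,1.87,2.977,1,4.223,5.269,0
45,2,2.88,4.243,0,,,0
46,1,1.007,2.422,1,2.93,4.031,0
46,2,0.473,1.992,0,,,0
47,1,3.744,4.852,1,7.404,8.739,0
47,2,0.7,2.308,0,,,0
48,1,2.32,3.744,1,2.15,3.403,0
48,2,5.052,6.17,0,,,0
49,1,0.215,0.871,1,0.66,1.9,0
49,2,3.107,4.482,0,,,0
50,1,0.107,1.094,1,5.824,6.756,1
51,1,1.96,3.16,1,3.424,4.137,0
52,1,3.225,3.84,1,3.462,4.612,0
52,2,3.72,4.885,0,,,0
53,1,0.925,2.51,1,2.76,3.951,0
53,2,2.117,3.668,0,,,0
54,1,3.491,4.029,1,1.777,3.081,1
54,2,0.87,2.556,0,,,1
55,1,2.302,3.419,1,2.906,4.159,0
55,2,1.857,3.147,0,,,0
56,1,3.594,4.479,1,2.223,3.535,0
56,2,1.198,1.957,0,,,0
57,1,4.172,5.665,1,0,0.735,0
57,2,0,1.037,0,,,0
58,1,0.862,1.857,1,2.43,3.731,0
58,2,2.607,3.853,0,,,0
59,1,2.148,2.985,1,2.657,3.077,0
59,2,0.917,2.464,0,,,0
60,1,2.408,3.328,1,4.35,5.044,0
60,2,0,0.984,0,,,0
61,1,0.707,1.629,1,4.136,5.215,0
61,2,0.4,2.071,0,,,0
62,1,2.844,4.278,1,1.788,3.127,0
63,1,0.642,1.192,1,7.827,8.76,0
63,2,2.31,3.039,1,2.557,3.458,0
64,1,1.034,2.519,1,5.875,7.215,0
64,2,1.451,2.703,0,,,0
65,1,0.767,2.379,1,5.905,7.062,0
65,2,2.078,2.753,0,,,0
66,1,5.23,6.378,1,1.479,2.568,0
66,2,5.341,6.883,0,,,0
67,1,1.808,2.607,1,5.085,6.015,0
68,1,0,0.776,1,3.275,4.437,0
68,2,1.498,2.403,0,,,0
69,1,2.401,3.077,1,2.851,4.233,0
69,2,0.897,2.192,0,,,0
70,1,2.057,3.631,1,4.318,5.368,0
70,2,3.561,4.165,0,,,0
71,1,4.033,5.54,1,4.675,5.269,0
71,2,4.866,6.101,0,,,0
72,1,0.846,1.733,1,7.871,8.729,0
72,2,1.709,2.988,0,,,0
73,1,1.539,2.566,1,3.074,4.349,0
73,2,1.195,1.993,0,,,0
74,1,2.562,4.248,1,3.267,4.347,0
74,2,3.195,4.622,0,,,0
75,1,1.854,3.511,1,4.082,4.993,0
75,2,3.777,5.277,0,,,0
76,1,2.395,3.386,1,4.254,5.254,1
76,2,2.373,3.196,0,,,1
77,1,5.351,6.373,1,0.856,1.662,0
77,2,0,0.658,0,,,0
78,1,0.162,1.603,1,4.377,4.825,0
78,2,5.298,6.788,0,,,0
79,1,2.862,4.504,1,4.477,5.211,1
79,2,5.325,6.527,0,,,1
80,1,3.951,5.223,1,3.761,4.823,0
80,2,0.578,1.32,0,,,0
81,1,0.636,1.491,0,,,0
81,2,2.327,3.964,1,2.86,3.322,0
81,3,0.412,1.553,1,4.067,4.834,0
82,1,1.972,3.609,1,5.741,6.811,0
82,2,2.797,3.567,0,,,0
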