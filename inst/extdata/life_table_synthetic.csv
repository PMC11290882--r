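age,sex,qx
0,male,0.004
1,male,0.00022859
2,male,0.00023144
3,male,0.00023457
4,male,0.00023802
5,male,0.00024181
6,male,0.00024597
7,male,0.00025056
8,male,0.0002556
9,male,0.00026114
10,male,0.00026723
11,male,0.00027393
12,male,0.0002813
13,male,0.0002894
14,male,0.00029831
15,male,0.0003081
16,male,0.00031888
17,male,0.00033073
18,male,0.00034375
19,male,0.00035808
20,male,0.00037383
21,male,0.00039116
22,male,0.00041021
23,male,0.00043116
24,male,0.00045419
25,male,0.00047953
26,male,0.00050738
27,male,0.00053802
28,male,0.0005717
29,male,0.00060875
30,male,0.00064948
31,male,0.00069428
32,male,0.00074354
33,male,0.0007977
34,male,0.00085727
35,male,0.00092277
36,male,0.0009948
37,male,0.001074
38,male,0.0011611
39,male,0.0012569
40,male,0.0013622
41,male,0.0014781
42,male,0.0016054
43,male,0.0017455
44,male,0.0018995
45,male,0.0020689
46,male,0.0022551
47,male,0.0024599
48,male,0.0026852
49,male,0.0029328
50,male,0.0032052
51,male,0.0035047
52,male,0.003834
53,male,0.0041962
54,male,0.0045944
55,male,0.0050324
56,male,0.005514
57,male,0.0060436
58,male,0.0066259
59,male,0.0072663
60,male,0.0079706
61,male,0.008745
62,male,0.0095965
63,male,0.010533
64,male,0.011563
65,male,0.012695
66,male,0.01394
67,male,0.01531
68,male,0.016816
69,male,0.018471
70,male,0.020292
71,male,0.022295
72,male,0.024497
73,male,0.026918
74,male,0.029581
75,male,0.032509
76,male,0.035729
77,male,0.039269
78,male,0.043163
79,male,0.047445
80,male,0.052153
81,male,0.057331
82,male,0.063024
83,male,0.069285
84,male,0.07617
85,male,0.083741
86,male,0.092067
87,male,0.10122
88,male,0.11129
89,male,0.12236
90,male,0.13454
91,male,0.14792
92,male,0.16265
93,male,0.17883
94,male,0.19664
95,male,0.21621
96,male,0.23774
97,male,0.26141
98,male,0.28745
99,male,0.31607
100,male,0.34755
101,male,0.38217
102,male,0.42024
103,male,0.4621
104,male,0.50813
105,male,0.55875
106,male,0.61441
107,male,0.67562
108,male,0.74294
109,male,0.81696
110,male,1
0,female,0.0035
1,female,0.00021869
2,female,0.00022056
3,female,0.00022261
4,female,0.00022486
5,female,0.00022734
6,female,0.00023006
7,female,0.00023306
8,female,0.00023635
9,female,0.00023997
10,female,0.00024396
11,female,0.00024834
12,female,0.00025316
13,female,0.00025845
14,female,0.00026428
15,female,0.00027068
16,female,0.00027773
17,female,0.00028547
18,female,0.00029399
19,female,0.00030336
20,female,0.00031366
21,female,0.00032499
22,female,0.00033744
23,female,0.00035114
24,female,0.0003662
25,female,0.00038277
26,female,0.00040098
27,female,0.00042101
28,female,0.00044304
29,female,0.00046726
30,female,0.00049389
31,female,0.00052318
32,female,0.00055539
33,female,0.00059081
34,female,0.00062975
35,female,0.00067258
36,female,0.00071968
37,female,0.00077147
38,female,0.00082842
39,female,0.00089105
40,female,0.00095992
41,female,0.0010357
42,female,0.0011189
43,female,0.0012105
44,female,0.0013112
45,female,0.001422
46,female,0.0015437
47,female,0.0016777
48,female,0.0018249
49,female,0.0019869
50,female,0.0021649
51,female,0.0023608
52,female,0.0025761
53,female,0.0028129
54,female,0.0030733
55,female,0.0033596
56,female,0.0036745
57,female,0.0040208
58,female,0.0044016
59,female,0.0048203
60,female,0.0052807
61,female,0.0057871
62,female,0.0063439
63,female,0.0069562
64,female,0.0076295
65,female,0.0083699
66,female,0.0091841
67,female,0.010079
68,female,0.011064
69,female,0.012147
70,female,0.013337
71,female,0.014647
72,female,0.016086
73,female,0.01767
74,female,0.019411
75,female,0.021325
76,female,0.02343
77,female,0.025745
78,female,0.028291
79,female,0.031091
80,female,0.034169
81,female,0.037555
82,female,0.041277
83,female,0.045371
84,female,0.049873
85,female,0.054823
86,female,0.060267
87,female,0.066253
88,female,0.072836
89,female,0.080075
90,female,0.088035
91,female,0.096788
92,female,0.10641
93,female,0.117
94,female,0.12864
95,female,0.14144
96,female,0.15552
97,female,0.17099
98,female,0.18802
99,female,0.20673
100,female,0.22732
101,female,0.24995
102,female,0.27484
103,female,0.30221
104,female,0.33231
105,female,0.3654
106,female,0.4018
107,female,0.44182
108,female,0.48584
109,female,0.53423
110,female,1
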