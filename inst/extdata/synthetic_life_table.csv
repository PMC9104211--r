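"age","qx"
0,6.0631718e-05
1,6.6010608e-05
2,7.1866665e-05
3,7.8242216e-05
4,8.518334e-05
5,9.2740206e-05
6,0.00010096743
7,0.00010992447
8,0.00011967606
9,0.00013029268
10,0.00014185105
11,0.00015443468
12,0.00016813452
13,0.00018304956
14,0.00019928756
15,0.00021696585
16,0.00023621215
17,0.00025716551
18,0.00027997728
19,0.00030481226
20,0.00033184982
21,0.00036128524
22,0.00039333111
23,0.00042821882
24,0.00046620028
25,0.0005075497
26,0.00055256558
27,0.00060157283
28,0.00065492512
29,0.00071300744
30,0.00077623881
31,0.00084507534
32,0.00092001345
33,0.0010015935
34,0.0010904034
35,0.0011870834
36,0.0012923299
37,0.0014069009
38,0.0015316214
39,0.001667389
40,0.0018151805
41,0.0019760588
42,0.0021511802
43,0.002341803
44,0.0025492959
45,0.0027751478
46,0.0030209785
47,0.0032885497
48,0.0035797774
49,0.0038967452
50,0.0042417188
51,0.0046171616
52,0.0050257517
53,0.0054704
54,0.0059542702
55,0.0064808003
56,0.0070537255
57,0.0076771033
58,0.0083553404
59,0.0090932216
60,0.0098959412
61,0.010769136
62,0.011718923
63,0.012751936
64,0.013875366
65,0.015097011
66,0.016425315
67,0.017869426
68,0.019439244
69,0.021145478
70,0.022999709
71,0.025014449
72,0.027203206
73,0.029580558
74,0.032162215
75,0.034965101
76,0.038007423
77,0.041308746
78,0.044890072
79,0.048773914
80,0.052984363
81,0.057547164
82,0.06248977
83,0.067841403
84,0.073633087
85,0.079897686
86,0.086669901
87,0.093986265
88,0.10188509
89,0.1104064
90,0.1195918
91,0.12948429
92,0.14012807
93,0.15156822
94,0.16385031
95,0.17701997
96,0.19112226
97,0.20620104
98,0.22229814
99,0.2394524
100,1
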