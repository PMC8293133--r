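age,q_annual
40,0.000898923001421911
41,0.000978672813295783
42,0.00106549779454885
43,0.00116002563345484
44,0.00126293970494991
45,0.00137498401099
46,0.00149696855920224
47,0.00162977521871439
48,0.00177436409549647
49,0.00193178047330387
50,0.00210316237040064
51,0.00228974876669303
52,0.00249288856075031
53,0.00271405032146607
54,0.00295483290485839
55,0.00321697701276134
56,0.0035023777769697
57,0.00381309845981211
58,0.00415138537019882
59,0.00451968410297751
60,0.00492065721899706
61,0.00535720349369477
62,0.00583247887336179
63,0.00634991929058683
64,0.00691326550381927
65,0.00752659014062534
66,0.00819432714014271
67,0.00892130380758324
68,0.00971277571251729
69,0.0105744646832313
70,0.0115126001718334
71,0.0125339642891499
72,0.0136459408349858
73,0.0148565686782056
74,0.0161745998725393
75,0.0176095629282513
76,0.0191718316970866
77,0.0208727003684875
78,0.0227244651192543
79,0.0247405130069246
80,0.0269354187495126
81,0.0293250500912624
82,0.0319266825161428
83,0.034759124138386
84,0.0378428516729491
85,0.0412001584688757
86,0.0448553156757436
87,0.0488347477083262
88,0.0531672232779653
89,0.0578840633716852
90,0.0630193676826053
91,0.0686102611285939
92,0.074697162241334
93,0.0813240753660795
94,0.0885389087845175
95,0.0963938210605571
96,0.1049455981129
97,0.114256063740386
98,0.124392526567938
99,0.135428266644248
100,0.147443065208974
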