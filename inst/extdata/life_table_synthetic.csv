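"age","sex","qx"
0,"male",0.00033
1,"male",0.000333
2,"male",0.000336
3,"male",0.000339
4,"male",0.000343
5,"male",0.000347
6,"male",0.000351
7,"male",0.000356
8,"male",0.000362
9,"male",0.000367
10,"male",0.000374
11,"male",0.000381
12,"male",0.000388
13,"male",0.000397
14,"male",0.000406
15,"male",0.000416
16,"male",0.000427
17,"male",0.000439
18,"male",0.000452
19,"male",0.000466
20,"male",0.000481
21,"male",0.000499
22,"male",0.000517
23,"male",0.000538
24,"male",0.00056
25,"male",0.000585
26,"male",0.000611
27,"male",0.000641
28,"male",0.000673
29,"male",0.000708
30,"male",0.000746
31,"male",0.000788
32,"male",0.000834
33,"male",0.000885
34,"male",0.00094
35,"male",0.001
36,"male",0.001066
37,"male",0.001138
38,"male",0.001217
39,"male",0.001303
40,"male",0.001398
41,"male",0.001501
42,"male",0.001614
43,"male",0.001738
44,"male",0.001874
45,"male",0.002022
46,"male",0.002184
47,"male",0.002362
48,"male",0.002556
49,"male",0.002768
50,"male",0.003001
51,"male",0.003255
52,"male",0.003533
53,"male",0.003838
54,"male",0.004171
55,"male",0.004535
56,"male",0.004934
57,"male",0.005371
58,"male",0.005848
59,"male",0.006371
60,"male",0.006942
61,"male",0.007568
62,"male",0.008252
63,"male",0.009001
64,"male",0.00982
65,"male",0.010717
66,"male",0.011698
67,"male",0.012771
68,"male",0.013946
69,"male",0.015231
70,"male",0.016637
71,"male",0.018176
72,"male",0.019859
73,"male",0.021701
74,"male",0.023717
75,"male",0.025922
76,"male",0.028335
77,"male",0.030975
78,"male",0.033864
79,"male",0.037024
80,"male",0.040483
81,"male",0.044267
82,"male",0.048408
83,"male",0.052938
84,"male",0.057895
85,"male",0.063319
86,"male",0.069254
87,"male",0.075748
88,"male",0.082853
89,"male",0.090628
90,"male",0.099134
91,"male",0.108442
92,"male",0.118626
93,"male",0.129769
94,"male",0.141962
95,"male",0.155303
96,"male",0.1699
97,"male",0.185872
98,"male",0.203348
99,"male",0.22247
0,"female",0.000218
1,"female",0.00022
2,"female",0.000222
3,"female",0.000224
4,"female",0.000226
5,"female",0.000229
6,"female",0.000231
7,"female",0.000234
8,"female",0.000238
9,"female",0.000241
10,"female",0.000245
11,"female",0.00025
12,"female",0.000254
13,"female",0.00026
14,"female",0.000265
15,"female",0.000272
16,"female",0.000278
17,"female",0.000286
18,"female",0.000294
19,"female",0.000303
20,"female",0.000313
21,"female",0.000324
22,"female",0.000336
23,"female",0.000349
24,"female",0.000364
25,"female",0.00038
26,"female",0.000397
27,"female",0.000416
28,"female",0.000437
29,"female",0.000459
30,"female",0.000484
31,"female",0.000512
32,"female",0.000542
33,"female",0.000575
34,"female",0.000611
35,"female",0.000651
36,"female",0.000694
37,"female",0.000742
38,"female",0.000794
39,"female",0.000851
40,"female",0.000914
41,"female",0.000982
42,"female",0.001058
43,"female",0.00114
44,"female",0.001231
45,"female",0.00133
46,"female",0.001439
47,"female",0.001559
48,"female",0.00169
49,"female",0.001833
50,"female",0.001991
51,"female",0.002163
52,"female",0.002352
53,"female",0.00256
54,"female",0.002787
55,"female",0.003037
56,"female",0.00331
57,"female",0.00361
58,"female",0.003938
59,"female",0.004298
60,"female",0.004693
61,"female",0.005126
62,"female",0.005601
63,"female",0.006122
64,"female",0.006692
65,"female",0.007318
66,"female",0.008004
67,"female",0.008756
68,"female",0.00958
69,"female",0.010484
70,"female",0.011475
71,"female",0.012562
72,"female",0.013753
73,"female",0.015059
74,"female",0.016491
75,"female",0.018061
76,"female",0.019782
77,"female",0.021669
78,"female",0.023738
79,"female",0.026006
80,"female",0.028493
81,"female",0.03122
82,"female",0.034209
83,"female",0.037486
84,"female",0.041079
85,"female",0.045018
86,"female",0.049337
87,"female",0.054072
88,"female",0.059264
89,"female",0.064955
90,"female",0.071195
91,"female",0.078037
92,"female",0.085538
93,"female",0.093761
94,"female",0.102777
95,"female",0.112662
96,"female",0.1235
97,"female",0.135381
98,"female",0.148408
99,"female",0.16269
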