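run,Rs1-2,Rs2-3,Rs3-4,Rs4-5,Rs5-6,Rs6-7,Rs7-8,time
1,FOP,FOP,1.2280,0.9515,0.6610,1.6360,0.7855,19.09
2,0.2555,1.1254,1.5789,1.5465,3.0378,2.7325,0.3874,21.18
3,FOP,FOP,1.5295,1.0145,0.5500,2.5180,1.0330,20.27
4,3.1026,1.2854,0.8438,2.6014,FOP,1.2804,0.8706,17.84
5,3.0046,1.2852,0.8660,2.6402,FOP,1.2772,0.8807,17.84
6,FOP,1.1549,1.6432,1.1495,3.1962,1.5370,0.9020,19.56
7,3.0033,1.9175,1.1825,3.2517,0.1641,1.1538,FOP,18.60
8,3.4380,1.2154,0.8799,2.4530,FOP,1.2758,0.9002,19.20
9,2.4517,0.9708,2.6548,1.7886,1.0280,FOP,0.9276,14.70
10,FOP,FOP,1.2460,1.4690,0.5300,2.3685,1.0175,22.76
11,3.2329,0.9794,2.1677,1.8457,1.2248,0.6605,0.9197,17.15
12,3.1698,1.3190,0.8337,2.5400,FOP,1.2681,0.8802,17.82
13,1.0052,1.4346,1.1752,1.3097,4.0203,2.2164,0.8106,16.67
14,0.6670,1.8968,1.7036,1.2585,3.4432,1.0378,1.1120,16.25
15,FOP,FOP,1.0430,1.2720,3.1895,3.1895,1.3860,25.40
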