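term,Rs1-2,Rs2-3,Rs3-4,Rs4-5,Rs5-6,Rs6-7,Rs7-8,time
constant,3.092,1.297,0.848,2.594,0.000,1.275,0.877,23.085
x1,-0.026,0.122,0.076,0.056,0.098,0.006,-0.121,-0.620
x2,-0.043,-0.051,0.384,-0.335,-0.008,-0.627,0.134,-3.039
x3,0.241,0.701,0.132,0.070,1.096,-0.274,-0.126,-0.617
x1x1,-0.020,-0.067,0.442,-0.140,0.044,-0.246,-0.084,-0.672
x1x2,-0.087,-0.178,0.046,-0.214,-0.097,-0.135,0.227,-0.774
x1x3,0.251,0.070,-0.188,0.154,0.201,0.132,-0.027,-0.025
x2x2,-0.041,0.041,0.432,-0.119,0.553,-0.257,-0.107,0.208
x2x3,0.103,0.193,-0.015,0.008,0.733,-0.035,0.331,0.085
x3x3,-2.821,-0.582,0.109,-1.218,2.030,1.131,0.147,0.366
R2,0.9743,0.9153,0.7414,0.9370,0.8794,0.9401,0.8679,0.9375
R2_adj,0.9281,0.7629,0.2758,0.8236,0.6624,0.8324,0.6301,0.8260
SE,0.4005,0.3234,0.4443,0.3008,0.8749,0.3461,0.1908,1.0064
MAE,0.1987,0.1477,0.1983,0.1392,0.3958,0.1577,0.0830,0.5456
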