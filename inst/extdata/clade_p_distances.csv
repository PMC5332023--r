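cladeA,cladeB,mean,sd,min,max,n
A,A,0.002,0.001,0,0.005,NA
B,B,0,0.0007,0,0.002,NA
C,C,0.007,0.006,0,0.026,NA
D,D,0.003,0.001,0,0.005,NA
E,E,0.004,0.003,0,0.008,NA
F,F,0.011,NA,NA,NA,NA
G,G,0.007,0.008,0,0.017,NA
H,H,0.007,0.004,0,0.017,NA
I,I,NA,NA,NA,NA,NA
A,B,0.057,0.001,0.052,0.058,35
A,C,0.096,0.003,0.084,0.1,52
A,D,0.106,0.001,0.101,0.104,10
A,E,0.128,0.002,0.121,0.131,12
A,F,0.094,0.001,0.088,0.094,8
A,G,0.109,0.004,0.094,0.111,11
A,H,0.096,0.003,0.085,0.101,34
A,I,0.12,0.001,0.119,0.122,8
B,C,0.067,0.002,0.059,0.075,75
B,D,0.106,0.048,0.101,0.108,33
B,E,0.132,0.0006,0.127,0.131,35
B,F,0.095,0.00007,0.0912,0.0916,31
B,G,0.109,0.003,0.097,0.107,34
B,H,0.098,0.002,0.091,0.107,57
B,I,0.135,0.0006,0.131,0.135,31
C,D,0.096,0.002,0.091,0.101,50
C,E,0.108,0.044,0.098,0.117,52
C,F,0.075,0.005,0.065,0.084,48
C,G,0.094,0.007,0.075,0.103,51
C,H,0.08,0.005,0.081,0.091,74
C,I,0.115,0.003,0.107,0.124,48
D,E,0.068,0.002,0.065,0.071,10
D,F,0.064,0.003,0.059,0.068,6
D,G,0.061,0.005,0.049,0.065,9
D,H,0.054,0.005,0.046,0.065,32
D,I,0.138,0.001,0.133,0.136,6
E,F,0.057,0.006,0.049,0.065,8
E,G,0.051,0.003,0.043,0.055,11
E,H,0.056,0.006,0.046,0.068,34
E,I,0.136,NA,NA,NA,8
F,G,0.038,0.007,0.02,0.044,7
F,H,0.025,0.005,0.02,0.037,30
F,I,0.142,0.0003,NA,NA,4
G,H,0.037,0.007,0.017,0.047,33
G,I,0.158,0.006,0.142,0.157,7
H,I,0.133,0.004,0.124,0.138,30
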