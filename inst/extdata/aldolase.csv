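wt,position,mt,effect,ddg_a,ddg_b,ddg_sum
I,74,T,Disease,0.50,0.29,0.79
R,134,S,Polymorphism,0.32,0.64,0.96
C,135,R,Disease,0.48,0.01,0.48
W,148,R,Unclassified,0.13,0.74,0.88
A,150,P,Disease,0.52,0.74,1.27
A,175,D,Disease,0.56,0.52,1.08
C,178,R,Disease,0.46,0.00,0.46
P,185,R,Disease,0.03,-0.01,0.03
E,207,Q,Polymorphism,0.35,0.15,0.49
V,222,F,Disease,0.32,0.61,0.93
L,229,P,Disease,0.86,0.85,1.72
L,257,P,Disease,0.80,0.69,1.49
I,268,N,Polymorphism,0.42,0.54,0.96
L,284,P,Disease,0.85,0.85,1.69
R,304,Q,Disease,0.39,0.22,0.61
R,304,W,Disease,0.27,0.24,0.52
N,335,K,Disease,-0.12,0.00,-0.12
A,338,V,Disease,0.20,0.07,0.27
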