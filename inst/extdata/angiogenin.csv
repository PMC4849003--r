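wt,position,mt,effect,ddg,location
Q,36,L,Disease,0.00,SUP
Y,38,H,Disease,-0.42,INT
K,41,E,Disease,1.04,SUR
K,41,I,Disease,0.29,SUR
D,46,G,Disease,-1.25,SUR
S,52,N,Disease,0.00,RIM-COR
R,55,K,Disease,1.29,COR
C,63,W,Disease,0.07,INT-SUP
K,64,I,Disease,4.50,COR
I,70,V,Unclassified,0.42,INT
K,84,E,Polymorphism,0.81,SUR
P,136,L,Disease,-0.06,INT
V,137,I,Disease,0.79,SUP
H,138,R,Disease,-1.32,COR
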