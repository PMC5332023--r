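clade,species,n,mean,sd,min,max
A,Dendropsophus arndti,13,30,1.5,28,32.4
B,Dendropsophus leucophyllatus,12,29.7,1.7,26.8,32.3
C,Dendropsophus reticulatus,185,23.8,1.5,20,29.6
D,Dendropsophus sp. D,3,30.7,0.9,29.8,31.5
E,Dendropsophus sp. E,3,27.3,2.1,25.2,29.4
F,Dendropsophus sp. F,2,29.9,0.3,29.7,30.2
G,Dendropsophus sp. G,5,30.5,0.9,29.5,31.6
H,Dendropsophus triangulum,26,31.7,1.5,28.6,34.4
I,Dendropsophus vraemi,8,26,0.9,25.1,27.6
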