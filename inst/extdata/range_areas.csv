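clade,species,area_km2,degraded_km2
B,Dendropsophus leucophyllatus,382451,NA
H,Dendropsophus triangulum,923514,52604
C,Dendropsophus reticulatus,390082,11093
A,Dendropsophus arndti,66397,3834
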