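clade,species,n_males,call_duration_s,n_notes,rise_time_call_s,n_pulses_call,typeI_duration_s,typeI_pulses,typeI_rise_s,typeII_duration_s,typeII_pulses,inter_note_s,dominant_freq_hz,bandwidth_hz
A,Dendropsophus arndti,7,0.19,1,0.12,17.44,0.2,17.44,0.12,NA,NA,NA,2655.37,487.67
B,Dendropsophus leucophyllatus,9,0.17,2.10,0.08,16.49,0.1,12.19,0.06,0.027,3.85,0.046,2748.69,530.32
C,Dendropsophus reticulatus,4,0.35,4.05,0.18,30.39,0.1,13.55,0.08,0.039,5.56,0.042,2992.39,705.98
D,Dendropsophus sp. D,4,0.21,1.10,0.15,18.43,0.21,18.03,0.15,0.004,0.4,0.001,2493.64,483.69
F,Dendropsophus sp. F,2,0.22,2.50,0.09,17,0.11,12.88,0.08,0.03,3.50,0.047,2660.63,581.39
G,Dendropsophus sp. G,5,0.28,3.28,0.09,24.40,0.11,13.92,0.08,0.033,4.5,0.041,2570.90,471.16
H,Dendropsophus triangulum,11,0.26,2.33,0.13,20.92,0.15,15.72,0.11,0.034,3.75,0.051,2456.43,478.34
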