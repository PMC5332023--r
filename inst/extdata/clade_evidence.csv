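lineage,acoustic_status,morpho_status
A,distinct,distinct
B,distinct,distinct
C,distinct,distinct
D,unavailable,unavailable
E,unavailable,unavailable
F,unavailable,unavailable
G,unavailable,unavailable
H,distinct,distinct
I,unavailable,distinct
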