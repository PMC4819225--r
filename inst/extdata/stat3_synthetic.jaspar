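>SYN0001 STAT3_synthetic
A [  5  2  1 25 25 25  2 90 90 ]
C [  5  2 95 25 25 25  2  4  4 ]
G [  5  2  1 25 25 25 90  4  4 ]
T [ 85 94  3 25 25 25  6  2  2 ]
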