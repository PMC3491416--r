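>SYN0001.1 AR_like_synthetic
A [ 17  1 17 17  1 17  5  5  5  1  1  1  1  1  1 ]
C [  1  1  1  1 17  1  5  5  5  1  1  1  1 17  1 ]
G [  1 17  1  1  1  1  5  5  5  1 17  1  1  1  1 ]
T [  1  1  1  1  1  1  5  5  5 17  1 17 17  1 17 ]
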