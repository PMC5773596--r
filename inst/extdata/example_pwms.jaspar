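>PM0001.1 CREB_like
A [  2  1 18  1  1  2 16  2 ]
C [  2  1  1 16  2  1  1  2 ]
G [  1 16  0  1  1 16  2  1 ]
T [ 15  2  1  2 16  1  1 15 ]
>PM0002.1 EBOX_like
A [  1  1 16  1  2  1 15  2 ]
C [ 16  2  1  1  1 16  1  2 ]
G [  1 15  1  2 16  1  2  1 ]
T [  2  2  2 16  1  2  2 15 ]
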