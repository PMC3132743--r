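>SYN0001 SYNTH_GC_BOX
A [  2  1  0  0  1  3 ]
C [  3 90  1  2 88  4 ]
G [ 92  5  1 95  6 90 ]
T [  3  4 98  3  5  3 ]
>SYN0002 SYNTH_AT_PALINDROME
A [ 88  2  5  3 90  1  4  2 ]
C [  4  3 88  2  2  3 90  3 ]
G [  5 92  3  4  4 91  2  5 ]
T [  3  3  4 91  4  5  4 90 ]
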