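
Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts
           A  R  N  D  C  Q  E  G  H  I  L  K  M  F  P  S  T  W  Y  V
    1 M    1  -1   1  -4  -4  -3   0   0   0   1  -1   3   6  -3   3  -2   0   1  -5   3
    2 K   -5  -3   1   2  -1  -2  -2  -1  -1  -5   0   8  -2   1  -3  -2  -1   1  -5   0
    3 V   -3   2  -4  -4   3  -5  -1   0  -5   1  -4   1  -5   1   2  -4   0  -4   1   8
    4 L   -4  -4  -2  -1  -3   0  -5   0   0  -3   5   3  -5  -5   1  -1   2  -1   2  -2
    5 A    7  -4   1  -2  -4  -3   0  -5  -1   0  -1  -1   3   3   0  -5  -2  -2   3  -2
    6 Y   -1   0   2   3  -4   2  -4   3   1   0  -5   2  -4  -5   2  -1   0  -1   6  -3
    7 G    0  -2  -3   0  -5  -1  -5   5   0  -1   2  -3   1  -2  -3  -2  -3   3  -4  -4
    8 F   -1  -1  -5   1  -1   1  -3  -5   2   3   1   0  -2   6  -1   1  -4   0   3   3
    9 T   -4   0  -2  -2  -1  -4   2   0  -4   0   3   3  -2   0  -5  -1   9  -3  -1  -5
   10 T    0   0   1  -5  -4   0  -3  -2   3  -1   2   3  -5   2   1  -3   7  -1   2   1

                      K         Lambda
Standard Ungapped    0.1380     0.3180
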