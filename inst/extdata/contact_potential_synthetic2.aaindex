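H SYNC020101
D Synthetic symmetric residue contact potential (substitute table 2);
D   deterministic stand-in, not an AAindex entry
M rows = ARNDCQEGHILKMFPSTWYV, cols = ARNDCQEGHILKMFPSTWYV
   -0.42
   -0.81   -1.62
   -1.98   -0.56    0.00
   -0.02    0.33   -0.76   -2.31
   -1.60    0.65   -0.82   -0.24    0.21
    0.53   -1.85   -0.64    0.11    1.24   -1.38
    1.10    0.90   -0.40   -0.19    1.24   -0.74   -1.34
    0.69   -2.09    0.37    0.08   -0.93    1.26   -0.06   -1.88
   -0.83    1.32   -2.16    0.74   -0.30    0.69    1.19   -2.16   -0.79
   -0.57   -0.53    0.85   -2.25   -1.78    0.50    0.78    1.29   -2.13    0.81
   -2.46    0.67   -1.58    1.17    0.03   -0.61   -1.87    1.06   -0.93    1.27   -2.39
   -0.78   -2.34   -1.40    1.33   -1.16   -2.32   -1.00    0.34    0.38    0.78   -2.03   -0.45
   -0.81   -0.81   -0.11   -2.10    0.96    0.80   -0.15   -1.29   -2.37   -0.20    1.32    1.36    0.87
    1.37    0.32   -1.29    0.53    0.45    0.17    0.71    0.87    1.19   -0.90    1.12   -2.16    0.38    0.05
   -1.25   -0.36   -0.98    0.58   -0.03    0.15    0.79   -1.59   -2.19    1.06    0.83   -1.57   -1.82    0.74   -1.79
   -0.91   -1.46   -1.82   -0.09    0.57   -0.76    0.17   -1.32   -1.65   -0.40   -2.10    1.30   -1.55    0.85   -0.92   -0.24
   -1.43   -1.53   -0.76   -0.64   -2.49    0.22   -1.25    0.19    0.61    1.24   -0.59   -1.15   -1.99   -0.18   -0.79   -0.64   -0.87
   -1.81   -0.75   -2.00    1.40   -2.42   -1.22   -1.27   -1.83   -0.23   -1.61   -2.49   -1.91   -0.70   -1.10   -2.35   -1.70   -2.25    0.90
   -1.04    0.91    0.51   -1.40    0.30   -0.47    0.07    1.26   -1.28    0.09   -1.40   -1.29   -0.96    1.32    1.39    0.15    1.22   -1.61   -0.46
    1.37   -1.55   -0.10   -0.96   -1.66   -2.07   -2.26   -0.12   -2.18    1.27   -1.48    0.56   -0.42    1.31   -1.77    1.10    0.62    1.04   -0.06   -1.49
//
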