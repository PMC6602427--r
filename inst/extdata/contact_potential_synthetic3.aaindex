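H SYNC030101
D Synthetic symmetric residue contact potential (substitute table 3);
D   deterministic stand-in, not an AAindex entry
M rows = ARNDCQEGHILKMFPSTWYV, cols = ARNDCQEGHILKMFPSTWYV
   -0.51
   -1.06    0.39
   -0.71   -0.69   -2.40
   -1.16   -0.60   -0.69   -2.15
   -1.32   -1.15    1.11    0.37    1.09
   -2.37   -1.59   -0.35   -2.25   -1.58   -0.26
   -2.50   -0.93   -2.37   -1.54    1.08   -0.95   -1.43
    1.15    0.92   -1.48   -0.79   -1.71    0.56   -0.68    0.58
    0.52   -1.97   -1.96    0.47    0.98   -1.78    0.93   -1.69   -1.14
    0.05   -1.90   -0.46   -0.76   -2.11   -2.26   -0.78   -0.49   -0.47   -2.24
   -0.77    1.41    0.33   -1.21    0.28   -0.92   -0.22   -1.99   -2.49    0.33   -0.66
   -2.31    1.50    0.01   -1.56   -0.48    0.72   -0.58    0.33   -2.47    0.70   -0.21   -1.08
   -0.86    1.00    1.27   -1.29    0.81   -1.18   -0.36   -2.27   -1.04   -0.53   -2.29    1.13    0.54
    1.12   -0.48   -1.75   -0.99   -2.22   -0.47   -0.61   -1.43    0.61    0.22    1.43   -0.88   -0.06   -1.91
   -0.94    0.35   -1.26    0.65   -0.43   -1.80   -2.10   -2.25   -0.06   -1.48   -1.18    1.05   -2.36   -0.60    0.20
   -1.60    1.36    1.05    0.06   -1.76   -1.30   -1.50   -1.54   -2.20    0.92    0.53   -2.38    1.30   -0.39    1.05   -1.24
    0.74   -1.96   -1.83   -0.36    0.30   -0.91    0.79   -1.21    1.26   -0.75    0.88    0.38   -1.77   -2.32   -0.89    0.66   -0.68
    0.25   -1.53    1.15   -1.08   -1.68   -2.21   -1.66   -1.96   -1.83   -2.49   -0.16    0.90   -1.12    1.48    1.25    0.10   -1.21    1.29
   -1.48   -1.35    0.88   -0.62    0.67   -0.80    0.29   -2.08   -0.96    1.26    0.96   -0.20   -0.36    1.41    1.07   -1.04   -0.94   -0.82   -0.78
    1.10   -0.59    0.65    0.78   -0.89   -0.89   -0.72    1.10    1.26    0.88   -0.15   -0.39    1.47   -0.89   -0.07   -0.41    0.41   -0.59    0.72    1.17
//
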