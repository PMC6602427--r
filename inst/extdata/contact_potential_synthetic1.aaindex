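H SYNC010101
D Synthetic symmetric residue contact potential (substitute table 1);
D   deterministic stand-in, not an AAindex entry
M rows = ARNDCQEGHILKMFPSTWYV, cols = ARNDCQEGHILKMFPSTWYV
    0.69
   -2.27    0.54
    0.95   -2.13    1.11
    0.64   -0.87   -1.00    0.10
   -0.90   -0.21   -0.07   -2.30    0.45
    0.33    1.19    0.36    0.12    0.45   -1.75
   -0.49    1.08    1.21   -2.42    1.01    0.05   -0.87
   -1.98    0.95   -1.48   -0.13   -2.20   -0.27   -0.93   -1.27
   -1.84   -2.36    0.99   -0.07   -2.48   -0.18    0.57   -1.70    1.22
    0.87   -0.35    1.45   -1.63   -2.35   -1.02   -1.77    1.28   -2.04   -1.09
    0.95   -2.34   -2.14   -0.42   -1.06   -2.41    0.18    0.87   -2.28   -1.99   -2.01
   -0.60    0.10   -1.44    0.81   -2.11    1.10   -1.60   -2.04   -1.69   -0.27    1.08   -2.07
   -0.06   -0.39   -0.60    0.64   -1.49    1.10   -1.18   -0.94   -0.49   -0.33    0.32    0.77    1.13
   -2.00   -1.76    0.57    0.64   -1.49    1.03    0.97   -2.25   -2.04   -2.12    0.96    0.98   -1.51    1.06
   -1.70   -0.63   -0.38   -0.20   -2.01   -2.26    1.06    0.63   -0.50    0.15    0.69   -2.25   -1.54    0.37    0.09
   -0.73   -1.94   -2.25   -1.38   -0.03   -0.71    0.03    1.21   -0.56   -1.47    1.07    1.36   -0.63    1.13   -0.75   -2.00
   -0.40    1.19    0.26   -1.65   -2.11    1.35    0.08   -0.10    0.39    1.08    0.59   -0.57   -1.83   -1.87   -0.33   -1.38    1.10
   -0.94    0.88   -2.49   -2.03    0.98   -0.32   -1.29   -0.09   -1.01   -0.25    1.05   -0.48    0.34   -0.71   -0.90   -0.12   -1.62   -0.38
    1.06    0.45   -1.09   -2.00   -2.31   -0.82   -1.69   -0.81   -1.68    0.49   -2.02    0.14   -0.88    0.29    1.39   -0.72   -2.25   -0.71    1.07
   -0.62   -0.03   -2.31   -2.08   -2.30    0.39   -1.11    1.07   -0.03   -2.22    1.47   -0.13   -2.37   -1.96    0.78    1.04    0.46   -1.82   -1.19   -0.08
//
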