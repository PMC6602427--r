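ATOM      1  N   ALA A   1       0.049   0.014   0.030  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.448  -0.020  -0.012  1.00  0.00           C
ATOM      3  C   ALA A   1       1.971   1.471   0.026  1.00  0.00           C
ATOM      4  O   ALA A   1       2.867   1.789  -0.780  1.00  0.00           O
ATOM      5  CB  ALA A   1       1.943  -0.672  -1.209  1.00  0.00           C
ATOM      6  N   PHE A   2       1.498   2.226   0.851  1.00  0.00           N
ATOM      7  CA  PHE A   2       1.892   3.669   0.926  1.00  0.00           C
ATOM      8  C   PHE A   2       1.825   4.372  -0.341  1.00  0.00           C
ATOM      9  O   PHE A   2       2.667   5.105  -0.773  1.00  0.00           O
ATOM     10  CB  PHE A   2       3.335   3.730   1.496  1.00  0.00           C
ATOM     11  CG  PHE A   2       3.419   3.039   2.831  1.00  0.00           C
ATOM     12  CD1 PHE A   2       3.707   1.689   2.894  1.00  0.00           C
ATOM     13  CD2 PHE A   2       3.213   3.756   3.995  1.00  0.00           C
ATOM     14  CE1 PHE A   2       3.783   1.055   4.120  1.00  0.00           C
ATOM     15  CE2 PHE A   2       3.287   3.121   5.220  1.00  0.00           C
ATOM     16  CZ  PHE A   2       3.574   1.770   5.282  1.00  0.00           C
ATOM     17  N   ALA A   3       0.596   4.233  -1.015  1.00  0.00           N
ATOM     18  CA  ALA A   3       0.354   4.823  -2.290  1.00  0.00           C
ATOM     19  C   ALA A   3       1.465   4.416  -3.308  1.00  0.00           C
ATOM     20  O   ALA A   3       1.943   5.263  -4.030  1.00  0.00           O
ATOM     21  CB  ALA A   3       0.405   6.356  -2.127  1.00  0.00           C
ATOM     22  N   ALA A   4       1.688   3.188  -3.427  1.00  0.00           N
ATOM     23  CA  ALA A   4       2.729   2.643  -4.387  1.00  0.00           C
ATOM     24  C   ALA A   4       4.028   3.340  -4.171  1.00  0.00           C
ATOM     25  O   ALA A   4       4.771   3.781  -5.104  1.00  0.00           O
ATOM     26  CB  ALA A   4       2.244   2.918  -5.808  1.00  0.00           C
ATOM     27  N   LYS B   1      -0.031  -0.039   4.773  1.00  0.00           N
ATOM     28  CA  LYS B   1       1.458  -0.038   4.764  1.00  0.00           C
ATOM     29  C   LYS B   1       2.036  -1.396   4.763  1.00  0.00           C
ATOM     30  O   LYS B   1       2.929  -1.773   5.548  1.00  0.00           O
ATOM     31  CB  LYS B   1       1.948   0.736   6.010  1.00  0.00           C
ATOM     32  CG  LYS B   1       1.486   2.194   5.948  1.00  0.00           C
ATOM     33  CD  LYS B   1       1.975   2.937   7.194  1.00  0.00           C
ATOM     34  CE  LYS B   1       1.513   4.394   7.133  1.00  0.00           C
ATOM     35  NZ  LYS B   1       1.983   5.108   8.328  1.00  0.00           N
ATOM     36  N   ALA B   2       1.485  -2.228   3.910  1.00  0.00           N
ATOM     37  CA  ALA B   2       1.905  -3.616   3.750  1.00  0.00           C
ATOM     38  C   ALA B   2       1.776  -4.399   5.181  1.00  0.00           C
ATOM     39  O   ALA B   2       2.684  -5.043   5.550  1.00  0.00           O
ATOM     40  CB  ALA B   2       3.367  -3.690   3.391  1.00  0.00           C
ATOM     41  N   ALA B   3       0.608  -4.199   5.767  1.00  0.00           N
ATOM     42  CA  ALA B   3       0.390  -4.798   7.085  1.00  0.00           C
ATOM     43  C   ALA B   3       1.472  -4.488   8.143  1.00  0.00           C
ATOM     44  O   ALA B   3       1.995  -5.263   8.782  1.00  0.00           O
ATOM     45  CB  ALA B   3       0.373  -6.390   6.900  1.00  0.00           C
ATOM     46  N   ALA B   4       1.736  -3.160   8.165  1.00  0.00           N
ATOM     47  CA  ALA B   4       2.717  -2.647   9.110  1.00  0.00           C
ATOM     48  C   ALA B   4       4.071  -3.297   8.874  1.00  0.00           C
ATOM     49  O   ALA B   4       4.734  -3.780   9.887  1.00  0.00           O
ATOM     50  CB  ALA B   4       2.306  -2.890  10.515  1.00  0.00           C
END
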