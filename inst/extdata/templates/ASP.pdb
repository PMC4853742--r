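REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   ASP A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  ASP A   1       0.435  -0.373  -0.016  1.00  0.00           C
ATOM      3  C   ASP A   1      -0.217   0.186   1.223  1.00  0.00           C
ATOM      4  O   ASP A   1      -0.859   1.209   1.159  1.00  0.00           O
ATOM      5  CB  ASP A   1       1.918   0.000  -0.023  1.00  0.00           C
ATOM      6  CG  ASP A   1       2.596  -0.661  -1.196  1.00  0.00           C
ATOM      7  OD1 ASP A   1       1.957  -1.360  -1.947  1.00  0.00           O
ATOM      8  OD2 ASP A   1       3.908  -0.475  -1.405  1.00  0.00           O
ATOM      9  OXT ASP A   1      -0.085  -0.450   2.397  1.00  0.00           O
ATOM     10  H   ASP A   1      -1.184  -0.100  -1.258  1.00  0.00           H
ATOM     11  H2  ASP A   1      -0.137   1.192  -1.225  1.00  0.00           H
ATOM     12  HA  ASP A   1       0.332  -1.458  -0.020  1.00  0.00           H
ATOM     13  HB2 ASP A   1       2.021   1.082  -0.108  1.00  0.00           H
ATOM     14  HB3 ASP A   1       2.383  -0.338   0.903  1.00  0.00           H
ATOM     15  HD2 ASP A   1       4.299  -0.920  -2.170  1.00  0.00           H
ATOM     16  HXT ASP A   1      -0.521  -0.052   3.164  1.00  0.00           H
END
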