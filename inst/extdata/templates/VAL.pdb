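REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   VAL A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  VAL A   1       0.434  -0.373  -0.015  1.00  0.00           C
ATOM      3  C   VAL A   1      -0.217   0.186   1.222  1.00  0.00           C
ATOM      4  O   VAL A   1      -0.703   1.292   1.202  1.00  0.00           O
ATOM      5  CB  VAL A   1       1.917   0.000  -0.024  1.00  0.00           C
ATOM      6  CG1 VAL A   1       2.579  -0.567  -1.281  1.00  0.00           C
ATOM      7  CG2 VAL A   1       2.060   1.522  -0.015  1.00  0.00           C
ATOM      8  OXT VAL A   1      -0.259  -0.544   2.347  1.00  0.00           O
ATOM      9  H   VAL A   1      -0.098   1.187  -1.159  1.00  0.00           H
ATOM     10  H2  VAL A   1       0.314  -0.131  -2.004  1.00  0.00           H
ATOM     11  HA  VAL A   1       0.333  -1.458  -0.021  1.00  0.00           H
ATOM     12  HB  VAL A   1       2.401  -0.416   0.861  1.00  0.00           H
ATOM     13 HG11 VAL A   1       3.637  -0.302  -1.287  1.00  0.00           H
ATOM     14 HG12 VAL A   1       2.477  -1.652  -1.286  1.00  0.00           H
ATOM     15 HG13 VAL A   1       2.096  -0.152  -2.164  1.00  0.00           H
ATOM     16 HG21 VAL A   1       1.577   1.938  -0.899  1.00  0.00           H
ATOM     17 HG22 VAL A   1       1.589   1.927   0.880  1.00  0.00           H
ATOM     18 HG23 VAL A   1       3.117   1.789  -0.020  1.00  0.00           H
ATOM     19  HXT VAL A   1      -0.677  -0.185   3.142  1.00  0.00           H
END
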