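REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   MET A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  MET A   1       0.435  -0.373  -0.015  1.00  0.00           C
ATOM      3  C   MET A   1      -0.217   0.186   1.222  1.00  0.00           C
ATOM      4  O   MET A   1      -0.703   1.291   1.203  1.00  0.00           O
ATOM      5  CB  MET A   1       1.918   0.000  -0.025  1.00  0.00           C
ATOM      6  CG  MET A   1       2.580  -0.567  -1.280  1.00  0.00           C
ATOM      7  SD  MET A   1       4.338  -0.125  -1.291  1.00  0.00           S
ATOM      8  CE  MET A   1       4.852  -0.905  -2.845  1.00  0.00           C
ATOM      9  OXT MET A   1      -0.258  -0.544   2.348  1.00  0.00           O
ATOM     10  H   MET A   1      -0.099   1.187  -1.160  1.00  0.00           H
ATOM     11  H2  MET A   1       0.314  -0.131  -2.004  1.00  0.00           H
ATOM     12  HA  MET A   1       0.333  -1.458  -0.021  1.00  0.00           H
ATOM     13  HB2 MET A   1       2.402  -0.414   0.860  1.00  0.00           H
ATOM     14  HB3 MET A   1       2.020   1.086  -0.019  1.00  0.00           H
ATOM     15  HG2 MET A   1       2.096  -0.152  -2.165  1.00  0.00           H
ATOM     16  HG3 MET A   1       2.478  -1.652  -1.286  1.00  0.00           H
ATOM     17  HE1 MET A   1       5.914  -0.729  -3.008  1.00  0.00           H
ATOM     18  HE2 MET A   1       4.665  -1.977  -2.792  1.00  0.00           H
ATOM     19  HE3 MET A   1       4.283  -0.477  -3.671  1.00  0.00           H
ATOM     20  HXT MET A   1      -0.677  -0.185   3.142  1.00  0.00           H
END
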