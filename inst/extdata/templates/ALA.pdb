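REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   ALA A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  ALA A   1       0.434  -0.372  -0.015  1.00  0.00           C
ATOM      3  C   ALA A   1      -0.217   0.186   1.222  1.00  0.00           C
ATOM      4  O   ALA A   1      -0.704   1.291   1.202  1.00  0.00           O
ATOM      5  CB  ALA A   1       1.917  -0.000  -0.023  1.00  0.00           C
ATOM      6  OXT ALA A   1      -0.259  -0.545   2.347  1.00  0.00           O
ATOM      7  H   ALA A   1      -0.099   1.187  -1.160  1.00  0.00           H
ATOM      8  H2  ALA A   1       0.314  -0.131  -2.004  1.00  0.00           H
ATOM      9  HA  ALA A   1       0.333  -1.458  -0.022  1.00  0.00           H
ATOM     10  HB1 ALA A   1       2.389  -0.405  -0.919  1.00  0.00           H
ATOM     11  HB2 ALA A   1       2.019   1.085  -0.018  1.00  0.00           H
ATOM     12  HB3 ALA A   1       2.401  -0.415   0.861  1.00  0.00           H
ATOM     13  HXT ALA A   1      -0.678  -0.186   3.142  1.00  0.00           H
END
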