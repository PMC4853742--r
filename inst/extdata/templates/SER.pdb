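REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   SER A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  SER A   1       0.435  -0.373  -0.015  1.00  0.00           C
ATOM      3  C   SER A   1      -0.217   0.186   1.222  1.00  0.00           C
ATOM      4  O   SER A   1      -0.703   1.291   1.203  1.00  0.00           O
ATOM      5  CB  SER A   1       1.917  -0.000  -0.024  1.00  0.00           C
ATOM      6  OG  SER A   1       2.536  -0.529  -1.198  1.00  0.00           O
ATOM      7  OXT SER A   1      -0.258  -0.545   2.347  1.00  0.00           O
ATOM      8  H   SER A   1      -0.100   1.186  -1.160  1.00  0.00           H
ATOM      9  H2  SER A   1       0.314  -0.131  -2.004  1.00  0.00           H
ATOM     10  HA  SER A   1       0.333  -1.458  -0.022  1.00  0.00           H
ATOM     11  HB2 SER A   1       2.019   1.085  -0.018  1.00  0.00           H
ATOM     12  HB3 SER A   1       2.401  -0.415   0.860  1.00  0.00           H
ATOM     13  HG  SER A   1       3.467  -0.272  -1.163  1.00  0.00           H
ATOM     14  HXT SER A   1      -0.677  -0.186   3.142  1.00  0.00           H
END
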