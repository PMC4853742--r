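REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   CYS A   1      -0.218   0.186  -1.206  1.00  0.00           N
ATOM      2  CA  CYS A   1       0.435  -0.373  -0.015  1.00  0.00           C
ATOM      3  C   CYS A   1      -0.218   0.186   1.222  1.00  0.00           C
ATOM      4  O   CYS A   1      -0.703   1.291   1.202  1.00  0.00           O
ATOM      5  CB  CYS A   1       1.917  -0.000  -0.023  1.00  0.00           C
ATOM      6  SG  CYS A   1       2.703  -0.672  -1.514  1.00  0.00           S
ATOM      7  OXT CYS A   1      -0.259  -0.545   2.347  1.00  0.00           O
ATOM      8  H   CYS A   1      -0.099   1.186  -1.160  1.00  0.00           H
ATOM      9  H2  CYS A   1       0.314  -0.131  -2.004  1.00  0.00           H
ATOM     10  HA  CYS A   1       0.333  -1.458  -0.022  1.00  0.00           H
ATOM     11  HB2 CYS A   1       2.019   1.085  -0.018  1.00  0.00           H
ATOM     12  HB3 CYS A   1       2.401  -0.415   0.861  1.00  0.00           H
ATOM     13  HG  CYS A   1       3.963  -0.243  -1.329  1.00  0.00           H
ATOM     14  HXT CYS A   1      -0.677  -0.186   3.141  1.00  0.00           H
END
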