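REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   TYR A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  TYR A   1       0.435  -0.373  -0.016  1.00  0.00           C
ATOM      3  C   TYR A   1      -0.217   0.186   1.223  1.00  0.00           C
ATOM      4  O   TYR A   1      -0.704   1.291   1.203  1.00  0.00           O
ATOM      5  CB  TYR A   1       1.917  -0.000  -0.024  1.00  0.00           C
ATOM      6  CG  TYR A   1       2.569  -0.559  -1.262  1.00  0.00           C
ATOM      7  CD1 TYR A   1       2.611   0.195  -2.420  1.00  0.00           C
ATOM      8  CD2 TYR A   1       3.130  -1.822  -1.236  1.00  0.00           C
ATOM      9  CE1 TYR A   1       3.207  -0.315  -3.556  1.00  0.00           C
ATOM     10  CE2 TYR A   1       3.724  -2.338  -2.371  1.00  0.00           C
ATOM     11  CZ  TYR A   1       3.767  -1.583  -3.536  1.00  0.00           C
ATOM     12  OH  TYR A   1       4.354  -2.088  -4.651  1.00  0.00           O
ATOM     13  OXT TYR A   1      -0.258  -0.546   2.347  1.00  0.00           O
ATOM     14  H   TYR A   1      -0.099   1.187  -1.159  1.00  0.00           H
ATOM     15  H2  TYR A   1       0.315  -0.131  -2.004  1.00  0.00           H
ATOM     16  HA  TYR A   1       0.333  -1.458  -0.022  1.00  0.00           H
ATOM     17  HB2 TYR A   1       2.020   1.084  -0.017  1.00  0.00           H
ATOM     18  HB3 TYR A   1       2.402  -0.416   0.860  1.00  0.00           H
ATOM     19  HD1 TYR A   1       2.177   1.183  -2.435  1.00  0.00           H
ATOM     20  HD2 TYR A   1       3.097  -2.409  -0.331  1.00  0.00           H
ATOM     21  HE1 TYR A   1       3.239   0.274  -4.461  1.00  0.00           H
ATOM     22  HE2 TYR A   1       4.157  -3.327  -2.353  1.00  0.00           H
ATOM     23  HH  TYR A   1       5.286  -1.831  -4.618  1.00  0.00           H
ATOM     24  HXT TYR A   1      -0.678  -0.187   3.142  1.00  0.00           H
END
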