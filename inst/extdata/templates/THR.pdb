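REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   THR A   1      -0.217   0.187  -1.207  1.00  0.00           N
ATOM      2  CA  THR A   1       0.435  -0.373  -0.015  1.00  0.00           C
ATOM      3  C   THR A   1      -0.217   0.187   1.222  1.00  0.00           C
ATOM      4  O   THR A   1      -0.703   1.292   1.203  1.00  0.00           O
ATOM      5  CB  THR A   1       1.918  -0.000  -0.025  1.00  0.00           C
ATOM      6  OG1 THR A   1       2.051   1.422  -0.017  1.00  0.00           O
ATOM      7  CG2 THR A   1       2.580  -0.567  -1.282  1.00  0.00           C
ATOM      8  OXT THR A   1      -0.258  -0.545   2.347  1.00  0.00           O
ATOM      9  H   THR A   1      -0.099   1.186  -1.160  1.00  0.00           H
ATOM     10  H2  THR A   1       0.313  -0.131  -2.005  1.00  0.00           H
ATOM     11  HA  THR A   1       0.332  -1.458  -0.022  1.00  0.00           H
ATOM     12  HB  THR A   1       2.402  -0.415   0.859  1.00  0.00           H
ATOM     13  HG1 THR A   1       1.611   1.748  -0.813  1.00  0.00           H
ATOM     14 HG21 THR A   1       3.636  -0.302  -1.287  1.00  0.00           H
ATOM     15 HG22 THR A   1       2.478  -1.653  -1.288  1.00  0.00           H
ATOM     16 HG23 THR A   1       2.096  -0.153  -2.165  1.00  0.00           H
ATOM     17  HXT THR A   1      -0.676  -0.186   3.141  1.00  0.00           H
END
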