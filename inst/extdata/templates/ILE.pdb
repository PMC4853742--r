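REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   ILE A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  ILE A   1       0.435  -0.372  -0.015  1.00  0.00           C
ATOM      3  C   ILE A   1      -0.217   0.186   1.222  1.00  0.00           C
ATOM      4  O   ILE A   1      -0.702   1.292   1.202  1.00  0.00           O
ATOM      5  CB  ILE A   1       1.917  -0.000  -0.025  1.00  0.00           C
ATOM      6  CG1 ILE A   1       2.579  -0.568  -1.281  1.00  0.00           C
ATOM      7  CG2 ILE A   1       2.597  -0.582   1.216  1.00  0.00           C
ATOM      8  CD1 ILE A   1       4.062  -0.195  -1.291  1.00  0.00           C
ATOM      9  OXT ILE A   1      -0.257  -0.543   2.348  1.00  0.00           O
ATOM     10  H   ILE A   1      -0.099   1.186  -1.160  1.00  0.00           H
ATOM     11  H2  ILE A   1       0.313  -0.132  -2.003  1.00  0.00           H
ATOM     12  HA  ILE A   1       0.333  -1.458  -0.020  1.00  0.00           H
ATOM     13  HB  ILE A   1       2.020   1.084  -0.018  1.00  0.00           H
ATOM     14 HG12 ILE A   1       2.096  -0.153  -2.165  1.00  0.00           H
ATOM     15 HG13 ILE A   1       2.478  -1.653  -1.287  1.00  0.00           H
ATOM     16 HG21 ILE A   1       2.495  -1.666   1.211  1.00  0.00           H
ATOM     17 HG22 ILE A   1       3.654  -0.316   1.210  1.00  0.00           H
ATOM     18 HG23 ILE A   1       2.127  -0.177   2.112  1.00  0.00           H
ATOM     19 HD11 ILE A   1       4.535  -0.599  -2.185  1.00  0.00           H
ATOM     20 HD12 ILE A   1       4.165   0.890  -1.284  1.00  0.00           H
ATOM     21 HD13 ILE A   1       4.546  -0.610  -0.407  1.00  0.00           H
ATOM     22  HXT ILE A   1      -0.675  -0.184   3.143  1.00  0.00           H
END
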