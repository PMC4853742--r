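REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   ASN A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  ASN A   1       0.434  -0.373  -0.016  1.00  0.00           C
ATOM      3  C   ASN A   1      -0.217   0.186   1.223  1.00  0.00           C
ATOM      4  O   ASN A   1      -0.858   1.208   1.159  1.00  0.00           O
ATOM      5  CB  ASN A   1       1.919   0.000  -0.024  1.00  0.00           C
ATOM      6  CG  ASN A   1       2.596  -0.660  -1.197  1.00  0.00           C
ATOM      7  OD1 ASN A   1       1.955  -1.361  -1.952  1.00  0.00           O
ATOM      8  ND2 ASN A   1       3.914  -0.473  -1.407  1.00  0.00           N
ATOM      9  OXT ASN A   1      -0.085  -0.451   2.397  1.00  0.00           O
ATOM     10  H   ASN A   1      -1.183  -0.099  -1.259  1.00  0.00           H
ATOM     11  H2  ASN A   1      -0.137   1.192  -1.225  1.00  0.00           H
ATOM     12  HA  ASN A   1       0.333  -1.458  -0.022  1.00  0.00           H
ATOM     13  HB2 ASN A   1       2.020   1.082  -0.108  1.00  0.00           H
ATOM     14  HB3 ASN A   1       2.383  -0.338   0.902  1.00  0.00           H
ATOM     15 HD21 ASN A   1       4.427   0.087  -0.803  1.00  0.00           H
ATOM     16 HD22 ASN A   1       4.351  -0.898  -2.161  1.00  0.00           H
ATOM     17  HXT ASN A   1      -0.521  -0.054   3.164  1.00  0.00           H
END
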