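REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   GLN A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  GLN A   1       0.435  -0.373  -0.015  1.00  0.00           C
ATOM      3  C   GLN A   1      -0.217   0.186   1.222  1.00  0.00           C
ATOM      4  O   GLN A   1      -0.704   1.291   1.202  1.00  0.00           O
ATOM      5  CB  GLN A   1       1.918  -0.000  -0.024  1.00  0.00           C
ATOM      6  CG  GLN A   1       2.579  -0.566  -1.281  1.00  0.00           C
ATOM      7  CD  GLN A   1       4.040  -0.199  -1.290  1.00  0.00           C
ATOM      8  OE1 GLN A   1       4.506   0.453  -0.380  1.00  0.00           O
ATOM      9  NE2 GLN A   1       4.829  -0.593  -2.308  1.00  0.00           N
ATOM     10  OXT GLN A   1      -0.257  -0.545   2.348  1.00  0.00           O
ATOM     11  H   GLN A   1      -0.100   1.187  -1.160  1.00  0.00           H
ATOM     12  H2  GLN A   1       0.313  -0.130  -2.004  1.00  0.00           H
ATOM     13  HA  GLN A   1       0.334  -1.457  -0.022  1.00  0.00           H
ATOM     14  HB2 GLN A   1       2.019   1.086  -0.018  1.00  0.00           H
ATOM     15  HB3 GLN A   1       2.401  -0.414   0.860  1.00  0.00           H
ATOM     16  HG2 GLN A   1       2.478  -1.652  -1.287  1.00  0.00           H
ATOM     17  HG3 GLN A   1       2.095  -0.152  -2.165  1.00  0.00           H
ATOM     18 HE21 GLN A   1       5.769  -0.357  -2.315  1.00  0.00           H
ATOM     19 HE22 GLN A   1       4.456  -1.114  -3.037  1.00  0.00           H
ATOM     20  HXT GLN A   1      -0.676  -0.186   3.143  1.00  0.00           H
END
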