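REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   GLU A   1      -0.217   0.187  -1.207  1.00  0.00           N
ATOM      2  CA  GLU A   1       0.434  -0.373  -0.016  1.00  0.00           C
ATOM      3  C   GLU A   1      -0.217   0.187   1.223  1.00  0.00           C
ATOM      4  O   GLU A   1      -0.858   1.209   1.159  1.00  0.00           O
ATOM      5  CB  GLU A   1       1.918   0.000  -0.023  1.00  0.00           C
ATOM      6  CG  GLU A   1       2.606  -0.672  -1.215  1.00  0.00           C
ATOM      7  CD  GLU A   1       4.068  -0.305  -1.223  1.00  0.00           C
ATOM      8  OE1 GLU A   1       4.514   0.420  -0.364  1.00  0.00           O
ATOM      9  OE2 GLU A   1       4.874  -0.782  -2.184  1.00  0.00           O
ATOM     10  OXT GLU A   1      -0.084  -0.450   2.397  1.00  0.00           O
ATOM     11  H   GLU A   1      -0.137   1.192  -1.226  1.00  0.00           H
ATOM     12  H2  GLU A   1       0.158  -0.221  -2.050  1.00  0.00           H
ATOM     13  HA  GLU A   1       0.332  -1.458  -0.021  1.00  0.00           H
ATOM     14  HB2 GLU A   1       2.021   1.082  -0.108  1.00  0.00           H
ATOM     15  HB3 GLU A   1       2.383  -0.338   0.902  1.00  0.00           H
ATOM     16  HG2 GLU A   1       2.504  -1.754  -1.131  1.00  0.00           H
ATOM     17  HG3 GLU A   1       2.141  -0.332  -2.140  1.00  0.00           H
ATOM     18  HE2 GLU A   1       5.804  -0.519  -2.147  1.00  0.00           H
ATOM     19  HXT GLU A   1      -0.521  -0.054   3.163  1.00  0.00           H
END
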