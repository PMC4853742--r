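REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   GLY A   1      -0.230  -0.170  -1.207  1.00  0.00           N
ATOM      2  CA  GLY A   1       0.461   0.341  -0.015  1.00  0.00           C
ATOM      3  C   GLY A   1      -0.230  -0.170   1.223  1.00  0.00           C
ATOM      4  O   GLY A   1      -1.198  -0.887   1.123  1.00  0.00           O
ATOM      5  OXT GLY A   1       0.230   0.171   2.437  1.00  0.00           O
ATOM      6  H   GLY A   1      -1.207   0.078  -1.193  1.00  0.00           H
ATOM      7  H2  GLY A   1       0.215   0.158  -2.051  1.00  0.00           H
ATOM      8  HA2 GLY A   1       1.495   0.000  -0.021  1.00  0.00           H
ATOM      9  HA3 GLY A   1       0.436   1.431  -0.021  1.00  0.00           H
ATOM     10  HXT GLY A   1      -0.246  -0.181   3.202  1.00  0.00           H
END
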