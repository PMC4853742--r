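REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   HIS A   1      -0.218   0.174  -1.206  1.00  0.00           N
ATOM      2  CA  HIS A   1       0.436  -0.348  -0.033  1.00  0.00           C
ATOM      3  C   HIS A   1      -0.218   0.174   1.239  1.00  0.00           C
ATOM      4  O   HIS A   1      -0.697   1.300   1.330  1.00  0.00           O
ATOM      5  CB  HIS A   1       1.930  -0.000  -0.032  1.00  0.00           C
ATOM      6  CG  HIS A   1       2.749  -0.919   0.842  1.00  0.00           C
ATOM      7  ND1 HIS A   1       2.953  -0.619   2.144  1.00  0.00           N
ATOM      8  CD2 HIS A   1       3.359  -2.071   0.543  1.00  0.00           C
ATOM      9  CE1 HIS A   1       3.700  -1.592   2.676  1.00  0.00           C
ATOM     10  NE2 HIS A   1       3.953  -2.482   1.711  1.00  0.00           N
ATOM     11  OXT HIS A   1      -0.243  -0.706   2.269  1.00  0.00           O
ATOM     12  H   HIS A   1      -0.959  -0.359  -1.629  1.00  0.00           H
ATOM     13  H2  HIS A   1       0.201   0.946  -1.697  1.00  0.00           H
ATOM     14  HA  HIS A   1       0.279  -1.432  -0.050  1.00  0.00           H
ATOM     15  HB2 HIS A   1       2.335  -0.050  -1.052  1.00  0.00           H
ATOM     16  HB3 HIS A   1       2.077   1.041   0.285  1.00  0.00           H
ATOM     17  HD1 HIS A   1       2.608   0.194   2.647  1.00  0.00           H
ATOM     18  HD2 HIS A   1       3.479  -2.696  -0.320  1.00  0.00           H
ATOM     19  HE1 HIS A   1       4.037  -1.648   3.699  1.00  0.00           H
ATOM     20  HE2 HIS A   1       4.500  -3.330   1.828  1.00  0.00           H
ATOM     21  HXT HIS A   1      -0.670  -0.372   3.085  1.00  0.00           H
END
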