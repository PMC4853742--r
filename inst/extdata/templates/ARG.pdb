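REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   ARG A   1      -0.231   0.177  -1.195  1.00  0.00           N
ATOM      2  CA  ARG A   1       0.462  -0.354  -0.023  1.00  0.00           C
ATOM      3  C   ARG A   1      -0.231   0.177   1.218  1.00  0.00           C
ATOM      4  O   ARG A   1      -1.160   0.975   1.227  1.00  0.00           O
ATOM      5  CB  ARG A   1       1.957  -0.000  -0.043  1.00  0.00           C
ATOM      6  CG  ARG A   1       2.257   1.505   0.038  1.00  0.00           C
ATOM      7  CD  ARG A   1       3.755   1.799   0.073  1.00  0.00           C
ATOM      8  NE  ARG A   1       4.408   1.303  -1.114  1.00  0.00           N
ATOM      9  CZ  ARG A   1       5.789   1.439  -1.343  1.00  0.00           C
ATOM     10  NH1 ARG A   1       6.375   0.944  -2.503  1.00  0.00           N
ATOM     11  NH2 ARG A   1       6.587   2.077  -0.399  1.00  0.00           N
ATOM     12  OXT ARG A   1       0.300  -0.341   2.358  1.00  0.00           O
ATOM     13  H   ARG A   1       0.019  -0.184  -2.090  1.00  0.00           H
ATOM     14  H2  ARG A   1      -0.769   1.008  -1.083  1.00  0.00           H
ATOM     15  HA  ARG A   1       0.344  -1.444  -0.035  1.00  0.00           H
ATOM     16  HB2 ARG A   1       2.407  -0.406  -0.958  1.00  0.00           H
ATOM     17  HB3 ARG A   1       2.453  -0.507   0.795  1.00  0.00           H
ATOM     18  HG2 ARG A   1       1.809   1.920   0.949  1.00  0.00           H
ATOM     19  HG3 ARG A   1       1.801   2.026  -0.812  1.00  0.00           H
ATOM     20  HD2 ARG A   1       3.914   2.882   0.131  1.00  0.00           H
ATOM     21  HD3 ARG A   1       4.216   1.352   0.961  1.00  0.00           H
ATOM     22  HE  ARG A   1       3.866   0.826  -1.845  1.00  0.00           H
ATOM     23 HH11 ARG A   1       7.374   1.042  -2.667  1.00  0.00           H
ATOM     24 HH12 ARG A   1       5.831   0.473  -3.222  1.00  0.00           H
ATOM     25 HH21 ARG A   1       6.191   2.449   0.460  1.00  0.00           H
ATOM     26 HH22 ARG A   1       7.588   2.185  -0.543  1.00  0.00           H
ATOM     27  HXT ARG A   1      -0.114  -0.032   3.192  1.00  0.00           H
END
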