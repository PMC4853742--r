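REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   LYS A   1      -0.217   0.187  -1.207  1.00  0.00           N
ATOM      2  CA  LYS A   1       0.434  -0.373  -0.015  1.00  0.00           C
ATOM      3  C   LYS A   1      -0.217   0.187   1.223  1.00  0.00           C
ATOM      4  O   LYS A   1      -0.858   1.209   1.159  1.00  0.00           O
ATOM      5  CB  LYS A   1       1.918   0.000  -0.023  1.00  0.00           C
ATOM      6  CG  LYS A   1       2.606  -0.672  -1.214  1.00  0.00           C
ATOM      7  CD  LYS A   1       4.090  -0.299  -1.222  1.00  0.00           C
ATOM      8  CE  LYS A   1       4.778  -0.971  -2.412  1.00  0.00           C
ATOM      9  NZ  LYS A   1       6.203  -0.614  -2.420  1.00  0.00           N
ATOM     10  OXT LYS A   1      -0.085  -0.451   2.397  1.00  0.00           O
ATOM     11  H   LYS A   1      -0.098   1.187  -1.160  1.00  0.00           H
ATOM     12  H2  LYS A   1       0.313  -0.131  -2.004  1.00  0.00           H
ATOM     13  HA  LYS A   1       0.332  -1.458  -0.021  1.00  0.00           H
ATOM     14  HB2 LYS A   1       2.021   1.081  -0.107  1.00  0.00           H
ATOM     15  HB3 LYS A   1       2.383  -0.339   0.903  1.00  0.00           H
ATOM     16  HG2 LYS A   1       2.503  -1.754  -1.129  1.00  0.00           H
ATOM     17  HG3 LYS A   1       2.142  -0.334  -2.140  1.00  0.00           H
ATOM     18  HD2 LYS A   1       4.193   0.783  -1.306  1.00  0.00           H
ATOM     19  HD3 LYS A   1       4.554  -0.638  -0.296  1.00  0.00           H
ATOM     20  HE2 LYS A   1       4.676  -2.053  -2.329  1.00  0.00           H
ATOM     21  HE3 LYS A   1       4.313  -0.633  -3.338  1.00  0.00           H
ATOM     22  HZ1 LYS A   1       6.297   0.388  -2.498  1.00  0.00           H
ATOM     23  HZ2 LYS A   1       6.633  -0.927  -1.563  1.00  0.00           H
ATOM     24  HZ3 LYS A   1       6.657  -1.056  -3.205  1.00  0.00           H
ATOM     25  HXT LYS A   1      -0.504  -0.092   3.192  1.00  0.00           H
END
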