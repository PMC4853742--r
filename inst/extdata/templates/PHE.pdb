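REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   PHE A   1      -0.217   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  PHE A   1       0.435  -0.372  -0.016  1.00  0.00           C
ATOM      3  C   PHE A   1      -0.217   0.186   1.223  1.00  0.00           C
ATOM      4  O   PHE A   1      -0.703   1.291   1.203  1.00  0.00           O
ATOM      5  CB  PHE A   1       1.918  -0.000  -0.025  1.00  0.00           C
ATOM      6  CG  PHE A   1       2.569  -0.558  -1.262  1.00  0.00           C
ATOM      7  CD1 PHE A   1       2.611   0.194  -2.421  1.00  0.00           C
ATOM      8  CD2 PHE A   1       3.130  -1.822  -1.238  1.00  0.00           C
ATOM      9  CE1 PHE A   1       3.209  -0.319  -3.556  1.00  0.00           C
ATOM     10  CE2 PHE A   1       3.724  -2.335  -2.375  1.00  0.00           C
ATOM     11  CZ  PHE A   1       3.765  -1.582  -3.534  1.00  0.00           C
ATOM     12  OXT PHE A   1      -0.258  -0.544   2.348  1.00  0.00           O
ATOM     13  H   PHE A   1      -0.099   1.187  -1.159  1.00  0.00           H
ATOM     14  H2  PHE A   1       0.313  -0.131  -2.003  1.00  0.00           H
ATOM     15  HA  PHE A   1       0.333  -1.457  -0.022  1.00  0.00           H
ATOM     16  HB2 PHE A   1       2.019   1.086  -0.018  1.00  0.00           H
ATOM     17  HB3 PHE A   1       2.402  -0.414   0.859  1.00  0.00           H
ATOM     18  HD1 PHE A   1       2.176   1.182  -2.438  1.00  0.00           H
ATOM     19  HD2 PHE A   1       3.099  -2.409  -0.332  1.00  0.00           H
ATOM     20  HE1 PHE A   1       3.241   0.269  -4.462  1.00  0.00           H
ATOM     21  HE2 PHE A   1       4.159  -3.324  -2.357  1.00  0.00           H
ATOM     22  HZ  PHE A   1       4.232  -1.984  -4.422  1.00  0.00           H
ATOM     23  HXT PHE A   1      -0.676  -0.186   3.142  1.00  0.00           H
END
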