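REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   PRO A   1      -0.207   0.196  -1.225  1.00  0.00           N
ATOM      2  CA  PRO A   1       0.414  -0.391  -0.009  1.00  0.00           C
ATOM      3  C   PRO A   1      -0.207   0.196   1.233  1.00  0.00           C
ATOM      4  O   PRO A   1      -0.845   1.219   1.164  1.00  0.00           O
ATOM      5  CB  PRO A   1       1.904  -0.000  -0.102  1.00  0.00           C
ATOM      6  CG  PRO A   1       2.162   0.242  -1.603  1.00  0.00           C
ATOM      7  CD  PRO A   1       0.806  -0.023  -2.291  1.00  0.00           C
ATOM      8  OXT PRO A   1      -0.050  -0.419   2.416  1.00  0.00           O
ATOM      9  H   PRO A   1      -1.001  -0.382  -1.456  1.00  0.00           H
ATOM     10  HA  PRO A   1       0.304  -1.475  -0.012  1.00  0.00           H
ATOM     11  HB2 PRO A   1       2.093   0.912   0.465  1.00  0.00           H
ATOM     12  HB3 PRO A   1       2.533  -0.812   0.264  1.00  0.00           H
ATOM     13  HG2 PRO A   1       2.477   1.272  -1.773  1.00  0.00           H
ATOM     14  HG3 PRO A   1       2.917  -0.452  -1.975  1.00  0.00           H
ATOM     15  HD2 PRO A   1       0.651   0.678  -3.112  1.00  0.00           H
ATOM     16  HD3 PRO A   1       0.757  -1.050  -2.653  1.00  0.00           H
ATOM     17  HXT PRO A   1      -0.448  -0.043   3.213  1.00  0.00           H
END
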