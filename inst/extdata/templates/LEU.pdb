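REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   LEU A   1      -0.217   0.187  -1.207  1.00  0.00           N
ATOM      2  CA  LEU A   1       0.434  -0.373  -0.015  1.00  0.00           C
ATOM      3  C   LEU A   1      -0.217   0.187   1.222  1.00  0.00           C
ATOM      4  O   LEU A   1      -0.703   1.292   1.203  1.00  0.00           O
ATOM      5  CB  LEU A   1       1.917  -0.000  -0.024  1.00  0.00           C
ATOM      6  CG  LEU A   1       2.579  -0.569  -1.281  1.00  0.00           C
ATOM      7  CD1 LEU A   1       4.063  -0.195  -1.290  1.00  0.00           C
ATOM      8  CD2 LEU A   1       2.436  -2.091  -1.289  1.00  0.00           C
ATOM      9  OXT LEU A   1      -0.258  -0.544   2.348  1.00  0.00           O
ATOM     10  H   LEU A   1      -0.099   1.186  -1.160  1.00  0.00           H
ATOM     11  H2  LEU A   1       0.313  -0.132  -2.004  1.00  0.00           H
ATOM     12  HA  LEU A   1       0.333  -1.458  -0.021  1.00  0.00           H
ATOM     13  HB2 LEU A   1       2.401  -0.414   0.860  1.00  0.00           H
ATOM     14  HB3 LEU A   1       2.020   1.085  -0.018  1.00  0.00           H
ATOM     15  HG  LEU A   1       2.096  -0.153  -2.164  1.00  0.00           H
ATOM     16 HD11 LEU A   1       4.534  -0.600  -2.185  1.00  0.00           H
ATOM     17 HD12 LEU A   1       4.165   0.890  -1.284  1.00  0.00           H
ATOM     18 HD13 LEU A   1       4.547  -0.609  -0.406  1.00  0.00           H
ATOM     19 HD21 LEU A   1       2.920  -2.505  -0.405  1.00  0.00           H
ATOM     20 HD22 LEU A   1       1.379  -2.356  -1.283  1.00  0.00           H
ATOM     21 HD23 LEU A   1       2.907  -2.496  -2.185  1.00  0.00           H
ATOM     22  HXT LEU A   1      -0.676  -0.185   3.142  1.00  0.00           H
END
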