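REMARK   1 SYNTHETIC TEMPLATE: CCD IDEAL COORDS, CANONICALIZED
ATOM      1  N   TRP A   1      -0.218   0.186  -1.207  1.00  0.00           N
ATOM      2  CA  TRP A   1       0.435  -0.373  -0.016  1.00  0.00           C
ATOM      3  C   TRP A   1      -0.218   0.186   1.223  1.00  0.00           C
ATOM      4  O   TRP A   1      -0.704   1.292   1.202  1.00  0.00           O
ATOM      5  CB  TRP A   1       1.918   0.000  -0.023  1.00  0.00           C
ATOM      6  CG  TRP A   1       2.569  -0.559  -1.262  1.00  0.00           C
ATOM      7  CD1 TRP A   1       2.683   0.055  -2.450  1.00  0.00           C
ATOM      8  CD2 TRP A   1       3.204  -1.871  -1.395  1.00  0.00           C
ATOM      9  NE1 TRP A   1       3.335  -0.760  -3.336  1.00  0.00           N
ATOM     10  CE2 TRP A   1       3.665  -1.948  -2.722  1.00  0.00           C
ATOM     11  CE3 TRP A   1       3.395  -2.949  -0.529  1.00  0.00           C
ATOM     12  CZ2 TRP A   1       4.318  -3.098  -3.151  1.00  0.00           C
ATOM     13  CZ3 TRP A   1       4.040  -4.069  -0.972  1.00  0.00           C
ATOM     14  CH2 TRP A   1       4.501  -4.148  -2.278  1.00  0.00           C
ATOM     15  OXT TRP A   1      -0.257  -0.544   2.348  1.00  0.00           O
ATOM     16  H   TRP A   1      -0.099   1.187  -1.159  1.00  0.00           H
ATOM     17  H2  TRP A   1       0.313  -0.131  -2.005  1.00  0.00           H
ATOM     18  HA  TRP A   1       0.333  -1.458  -0.021  1.00  0.00           H
ATOM     19  HB2 TRP A   1       2.019   1.085  -0.018  1.00  0.00           H
ATOM     20  HB3 TRP A   1       2.402  -0.415   0.860  1.00  0.00           H
ATOM     21  HD1 TRP A   1       2.316   1.044  -2.675  1.00  0.00           H
ATOM     22  HE1 TRP A   1       3.535  -0.535  -4.257  1.00  0.00           H
ATOM     23  HE3 TRP A   1       3.039  -2.896   0.489  1.00  0.00           H
ATOM     24  HZ2 TRP A   1       4.679  -3.169  -4.167  1.00  0.00           H
ATOM     25  HZ3 TRP A   1       4.193  -4.901  -0.300  1.00  0.00           H
ATOM     26  HH2 TRP A   1       5.008  -5.040  -2.615  1.00  0.00           H
ATOM     27  HXT TRP A   1      -0.677  -0.186   3.142  1.00  0.00           H
END
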