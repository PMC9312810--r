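REMARK synthetic three-residue fixture
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O
ATOM      5  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N
ATOM      6  CA  GLY A   2       3.988   2.839   0.000  1.00  0.00           C
ATOM      7  C   GLY A   2       5.504   2.693   0.000  1.00  0.00           C
ATOM      8  O   GLY A   2       6.030   1.581   0.000  1.00  0.00           O
ATOM      9  N   SER A   3       6.235   3.801   0.000  1.00  0.00           N
ATOM     10  CA  SER A   3       7.689   3.790   0.000  1.00  0.00           C
ATOM     11  C   SER A   3       8.251   5.203   0.000  1.00  0.00           C
ATOM     12  O   SER A   3       7.511   6.191   0.000  1.00  0.00           O
END
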