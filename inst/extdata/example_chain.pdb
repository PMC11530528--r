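ATOM      1  N   ALA A   1       0.256   2.176   1.500  1.00  0.00           N
ATOM      2  CA  ALA A   1      -0.744   2.176   1.500  1.00  0.00           C
ATOM      3  N   CYS A   2      -0.819  -1.407   3.000  1.00  0.00           N
ATOM      4  CA  CYS A   2      -1.819  -1.407   3.000  1.00  0.00           C
ATOM      5  N   ASP A   3       2.920  -1.267   4.500  1.00  0.00           N
ATOM      6  CA  ASP A   3       1.920  -1.267   4.500  1.00  0.00           C
ATOM      7  N   GLU A   4       1.578   2.226   6.000  1.00  0.00           N
ATOM      8  CA  GLU A   4       0.578   2.226   6.000  1.00  0.00           C
ATOM      9  N   PHE A   5      -1.293  -0.173   7.500  1.00  0.00           N
ATOM     10  CA  PHE A   5      -2.293  -0.173   7.500  1.00  0.00           C
ATOM     11  N   GLY A   6       1.905  -2.114   9.000  1.00  0.00           N
ATOM     12  CA  GLY A   6       0.905  -2.114   9.000  1.00  0.00           C
ATOM     13  N   HIS A   7       2.708   1.540  10.500  1.00  0.00           N
ATOM     14  CA  HIS A   7       1.708   1.540  10.500  1.00  0.00           C
ATOM     15  N   ILE A   8      -1.010   1.119  12.000  1.00  0.00           N
ATOM     16  CA  ILE A   8      -2.010   1.119  12.000  1.00  0.00           C
ATOM     17  N   LYS A   9       0.591  -2.263  13.500  1.00  0.00           N
ATOM     18  CA  LYS A   9      -0.409  -2.263  13.500  1.00  0.00           C
ATOM     19  N   LEU A  10       3.274   0.345  15.000  1.00  0.00           N
ATOM     20  CA  LEU A  10       2.274   0.345  15.000  1.00  0.00           C
ATOM     21  N   MET A  11      -0.061   2.040  16.500  1.00  0.00           N
ATOM     22  CA  MET A  11      -1.061   2.040  16.500  1.00  0.00           C
ATOM     23  N   ASN A  12      -0.588  -1.664  18.000  1.00  0.00           N
ATOM     24  CA  ASN A  12      -1.588  -1.664  18.000  1.00  0.00           C
END
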