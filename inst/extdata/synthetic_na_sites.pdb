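REMARK   SYNTHETIC fixture: an idealised pair of sodium-site ions placed
REMARK   7.0 Angstrom apart (the crystallographic Na1-Na2 separation of the
REMARK   occluded LeuT structure), with a minimal peptide stub. This is a
REMARK   constructed stand-in, not deposited coordinates.
ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.100   1.380   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       1.450   2.420   0.000  1.00  0.00           O
ATOM      5  CB  ALA A   1       1.950  -0.780   1.220  1.00  0.00           C
HETATM    6 NA    NA A 601       4.000   2.000   3.000  1.00  0.00          NA
HETATM    7 NA    NA A 602       8.200   7.600   3.000  1.00  0.00          NA
END
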