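# Example region specification for counting waters in a transporter's
# extracellular vestibule. The lining-residue list below is ILLUSTRATIVE
# (a sample of extracellular-section residues); the vestibule boundary is
# study-specific and must be supplied explicitly by the user — absolute
# water counts depend on it.
mode: convex_hull
lining_residues: [24, 29, 33, 104, 108, 112, 254, 258, 286, 290, 306, 308, 316, 320, 404, 408]
water_resnames: [HOH, TIP3, WAT, SOL]
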