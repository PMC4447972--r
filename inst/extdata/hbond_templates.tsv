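resname	atom	role
SER	OG	both
THR	OG1	both
TYR	OH	both
CYS	SG	both
ASN	OD1	acceptor
ASN	ND2	donor
GLN	OE1	acceptor
GLN	NE2	donor
ASP	OD1	acceptor
ASP	OD2	acceptor
GLU	OE1	acceptor
GLU	OE2	acceptor
LYS	NZ	donor
ARG	NE	donor
ARG	NH1	donor
ARG	NH2	donor
HIS	ND1	both
HIS	NE2	both
HSD	ND1	both
HSD	NE2	both
HSE	ND1	both
HSE	NE2	both
TRP	NE1	donor
MET	SD	acceptor
HOH	O	both
HOH	OW	both
TIP3	OH2	both
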