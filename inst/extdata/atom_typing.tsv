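res_name	atom_name	labels
ANY	N	donor
PRO	N
ANY	CA
ANY	C
ANY	O	acceptor
ANY	OXT	acceptor
ALA	CB	hydrophobic
ARG	CB	hydrophobic
ARG	CG	hydrophobic
ARG	CD
ARG	NE	positive;donor
ARG	CZ
ARG	NH1	positive;donor
ARG	NH2	positive;donor
ASN	CB	hydrophobic
ASN	CG
ASN	OD1	acceptor
ASN	ND2	donor
ASP	CB	hydrophobic
ASP	CG
ASP	OD1	negative;acceptor
ASP	OD2	negative;acceptor
CYS	CB
CYS	SG	cysteine
GLN	CB	hydrophobic
GLN	CG	hydrophobic
GLN	CD
GLN	OE1	acceptor
GLN	NE2	donor
GLU	CB	hydrophobic
GLU	CG	hydrophobic
GLU	CD
GLU	OE1	negative;acceptor
GLU	OE2	negative;acceptor
HIS	CB	hydrophobic
HIS	CG	aromatic
HIS	ND1	aromatic;positive;donor;acceptor
HIS	CD2	aromatic
HIS	CE1	aromatic
HIS	NE2	aromatic;positive;donor;acceptor
ILE	CB	hydrophobic
ILE	CG1	hydrophobic
ILE	CG2	hydrophobic
ILE	CD1	hydrophobic
LEU	CB	hydrophobic
LEU	CG	hydrophobic
LEU	CD1	hydrophobic
LEU	CD2	hydrophobic
LYS	CB	hydrophobic
LYS	CG	hydrophobic
LYS	CD	hydrophobic
LYS	CE
LYS	NZ	positive;donor
MET	CB	hydrophobic
MET	CG
MET	SD	hydrophobic
MET	CE
PHE	CB	hydrophobic
PHE	CG	aromatic
PHE	CD1	aromatic
PHE	CD2	aromatic
PHE	CE1	aromatic
PHE	CE2	aromatic
PHE	CZ	aromatic
PRO	CB	hydrophobic
PRO	CG	hydrophobic
PRO	CD
SER	CB
SER	OG	donor;acceptor
THR	CB
THR	OG1	donor;acceptor
THR	CG2	hydrophobic
TRP	CB	hydrophobic
TRP	CG	aromatic
TRP	CD1	aromatic
TRP	CD2	aromatic
TRP	NE1	aromatic;donor
TRP	CE2	aromatic
TRP	CE3	aromatic
TRP	CZ2	aromatic
TRP	CZ3	aromatic
TRP	CH2	aromatic
TYR	CB	hydrophobic
TYR	CG	aromatic
TYR	CD1	aromatic
TYR	CD2	aromatic
TYR	CE1	aromatic
TYR	CE2	aromatic
TYR	CZ	aromatic
TYR	OH	donor;acceptor
VAL	CB	hydrophobic
VAL	CG1	hydrophobic
VAL	CG2	hydrophobic
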