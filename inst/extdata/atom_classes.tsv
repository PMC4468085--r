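res_type	atom	class
*	N	donor
*	CA	neutral
*	C	neutral
*	O	acceptor
*	OXT	acceptor
*	CB	hydrophobic
*	CB2	hydrophobic
*	CG2	hydrophobic
*	CD2	hydrophobic
*	CE2	hydrophobic
*	CH2	hydrophobic
ALA	CB	hydrophobic
ARG	CG	hydrophobic
ARG	CD	neutral
ARG	NE	donor
ARG	CZ	neutral
ARG	NH1	donor
ARG	NH2	donor
ASN	CG	neutral
ASN	OD1	acceptor
ASN	ND2	donor
ASP	CG	neutral
ASP	OD1	acceptor
ASP	OD2	acceptor
CYS	SG	neutral-donor
GLN	CG	hydrophobic
GLN	CD	neutral
GLN	OE1	acceptor
GLN	NE2	donor
GLU	CG	hydrophobic
GLU	CD	neutral
GLU	OE1	acceptor
GLU	OE2	acceptor
HIS	CG	aromatic
HIS	ND1	neutral-acceptor
HIS	CD2	aromatic
HIS	CE1	aromatic
HIS	NE2	donor
ILE	CG1	hydrophobic
ILE	CG2	hydrophobic
ILE	CD1	hydrophobic
ILE	CD	hydrophobic
LEU	CG	hydrophobic
LEU	CD1	hydrophobic
LEU	CD2	hydrophobic
LYS	CG	hydrophobic
LYS	CD	hydrophobic
LYS	CE	neutral
LYS	NZ	donor
MET	CG	hydrophobic
MET	SD	acceptor
MET	CE	hydrophobic
PHE	CG	aromatic
PHE	CD1	aromatic
PHE	CD2	aromatic
PHE	CE1	aromatic
PHE	CE2	aromatic
PHE	CZ	aromatic
PRO	CG	hydrophobic
PRO	CD	neutral
SER	OG	hydrophilic
THR	OG1	hydrophilic
TRP	CG	aromatic
TRP	CD1	aromatic
TRP	CD2	aromatic
TRP	NE1	donor
TRP	CE2	aromatic
TRP	CE3	aromatic
TRP	CZ2	aromatic
TRP	CZ3	aromatic
TRP	CH2	aromatic
TYR	CG	aromatic
TYR	CD1	aromatic
TYR	CD2	aromatic
TYR	CE1	aromatic
TYR	CE2	aromatic
TYR	CZ	aromatic
TYR	OH	hydrophilic
VAL	CG1	hydrophobic
VAL	CG2	hydrophobic
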