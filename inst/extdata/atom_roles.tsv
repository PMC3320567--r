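resname	atomname	backbone	polarity
ALA	N	TRUE	donor
ALA	CA	TRUE	other_polar
ALA	C	TRUE	other_polar
ALA	O	TRUE	acceptor
ALA	OXT	TRUE	acceptor
ALA	CB	FALSE	apolar
ARG	N	TRUE	donor
ARG	CA	TRUE	other_polar
ARG	C	TRUE	other_polar
ARG	O	TRUE	acceptor
ARG	OXT	TRUE	acceptor
ARG	CB	FALSE	apolar
ARG	CG	FALSE	apolar
ARG	CD	FALSE	other_polar
ARG	NE	FALSE	charged_positive
ARG	CZ	FALSE	other_polar
ARG	NH1	FALSE	charged_positive
ARG	NH2	FALSE	charged_positive
ASN	N	TRUE	donor
ASN	CA	TRUE	other_polar
ASN	C	TRUE	other_polar
ASN	O	TRUE	acceptor
ASN	OXT	TRUE	acceptor
ASN	CB	FALSE	apolar
ASN	CG	FALSE	other_polar
ASN	OD1	FALSE	acceptor
ASN	ND2	FALSE	donor
ASP	N	TRUE	donor
ASP	CA	TRUE	other_polar
ASP	C	TRUE	other_polar
ASP	O	TRUE	acceptor
ASP	OXT	TRUE	acceptor
ASP	CB	FALSE	apolar
ASP	CG	FALSE	other_polar
ASP	OD1	FALSE	charged_negative
ASP	OD2	FALSE	charged_negative
CYS	N	TRUE	donor
CYS	CA	TRUE	other_polar
CYS	C	TRUE	other_polar
CYS	O	TRUE	acceptor
CYS	OXT	TRUE	acceptor
CYS	CB	FALSE	apolar
CYS	SG	FALSE	apolar
GLN	N	TRUE	donor
GLN	CA	TRUE	other_polar
GLN	C	TRUE	other_polar
GLN	O	TRUE	acceptor
GLN	OXT	TRUE	acceptor
GLN	CB	FALSE	apolar
GLN	CG	FALSE	apolar
GLN	CD	FALSE	other_polar
GLN	OE1	FALSE	acceptor
GLN	NE2	FALSE	donor
GLU	N	TRUE	donor
GLU	CA	TRUE	other_polar
GLU	C	TRUE	other_polar
GLU	O	TRUE	acceptor
GLU	OXT	TRUE	acceptor
GLU	CB	FALSE	apolar
GLU	CG	FALSE	apolar
GLU	CD	FALSE	other_polar
GLU	OE1	FALSE	charged_negative
GLU	OE2	FALSE	charged_negative
GLY	N	TRUE	donor
GLY	CA	TRUE	other_polar
GLY	C	TRUE	other_polar
GLY	O	TRUE	acceptor
GLY	OXT	TRUE	acceptor
HIS	N	TRUE	donor
HIS	CA	TRUE	other_polar
HIS	C	TRUE	other_polar
HIS	O	TRUE	acceptor
HIS	OXT	TRUE	acceptor
HIS	CB	FALSE	apolar
HIS	CG	FALSE	other_polar
HIS	ND1	FALSE	donor_and_acceptor
HIS	CD2	FALSE	other_polar
HIS	CE1	FALSE	other_polar
HIS	NE2	FALSE	donor_and_acceptor
ILE	N	TRUE	donor
ILE	CA	TRUE	other_polar
ILE	C	TRUE	other_polar
ILE	O	TRUE	acceptor
ILE	OXT	TRUE	acceptor
ILE	CB	FALSE	apolar
ILE	CG1	FALSE	apolar
ILE	CG2	FALSE	apolar
ILE	CD1	FALSE	apolar
LEU	N	TRUE	donor
LEU	CA	TRUE	other_polar
LEU	C	TRUE	other_polar
LEU	O	TRUE	acceptor
LEU	OXT	TRUE	acceptor
LEU	CB	FALSE	apolar
LEU	CG	FALSE	apolar
LEU	CD1	FALSE	apolar
LEU	CD2	FALSE	apolar
LYS	N	TRUE	donor
LYS	CA	TRUE	other_polar
LYS	C	TRUE	other_polar
LYS	O	TRUE	acceptor
LYS	OXT	TRUE	acceptor
LYS	CB	FALSE	apolar
LYS	CG	FALSE	apolar
LYS	CD	FALSE	apolar
LYS	CE	FALSE	other_polar
LYS	NZ	FALSE	charged_positive
MET	N	TRUE	donor
MET	CA	TRUE	other_polar
MET	C	TRUE	other_polar
MET	O	TRUE	acceptor
MET	OXT	TRUE	acceptor
MET	CB	FALSE	apolar
MET	CG	FALSE	apolar
MET	SD	FALSE	apolar
MET	CE	FALSE	apolar
PHE	N	TRUE	donor
PHE	CA	TRUE	other_polar
PHE	C	TRUE	other_polar
PHE	O	TRUE	acceptor
PHE	OXT	TRUE	acceptor
PHE	CB	FALSE	apolar
PHE	CG	FALSE	apolar
PHE	CD1	FALSE	apolar
PHE	CD2	FALSE	apolar
PHE	CE1	FALSE	apolar
PHE	CE2	FALSE	apolar
PHE	CZ	FALSE	apolar
PRO	N	TRUE	other_polar
PRO	CA	TRUE	other_polar
PRO	C	TRUE	other_polar
PRO	O	TRUE	acceptor
PRO	OXT	TRUE	acceptor
PRO	CB	FALSE	apolar
PRO	CG	FALSE	apolar
PRO	CD	FALSE	other_polar
SER	N	TRUE	donor
SER	CA	TRUE	other_polar
SER	C	TRUE	other_polar
SER	O	TRUE	acceptor
SER	OXT	TRUE	acceptor
SER	CB	FALSE	other_polar
SER	OG	FALSE	donor_and_acceptor
THR	N	TRUE	donor
THR	CA	TRUE	other_polar
THR	C	TRUE	other_polar
THR	O	TRUE	acceptor
THR	OXT	TRUE	acceptor
THR	CB	FALSE	other_polar
THR	OG1	FALSE	donor_and_acceptor
THR	CG2	FALSE	apolar
TRP	N	TRUE	donor
TRP	CA	TRUE	other_polar
TRP	C	TRUE	other_polar
TRP	O	TRUE	acceptor
TRP	OXT	TRUE	acceptor
TRP	CB	FALSE	apolar
TRP	CG	FALSE	apolar
TRP	CD1	FALSE	other_polar
TRP	CD2	FALSE	apolar
TRP	NE1	FALSE	donor
TRP	CE2	FALSE	other_polar
TRP	CE3	FALSE	apolar
TRP	CZ2	FALSE	apolar
TRP	CZ3	FALSE	apolar
TRP	CH2	FALSE	apolar
TYR	N	TRUE	donor
TYR	CA	TRUE	other_polar
TYR	C	TRUE	other_polar
TYR	O	TRUE	acceptor
TYR	OXT	TRUE	acceptor
TYR	CB	FALSE	apolar
TYR	CG	FALSE	apolar
TYR	CD1	FALSE	apolar
TYR	CD2	FALSE	apolar
TYR	CE1	FALSE	apolar
TYR	CE2	FALSE	apolar
TYR	CZ	FALSE	other_polar
TYR	OH	FALSE	donor_and_acceptor
VAL	N	TRUE	donor
VAL	CA	TRUE	other_polar
VAL	C	TRUE	other_polar
VAL	O	TRUE	acceptor
VAL	OXT	TRUE	acceptor
VAL	CB	FALSE	apolar
VAL	CG1	FALSE	apolar
VAL	CG2	FALSE	apolar
PTR	N	TRUE	donor
PTR	CA	TRUE	other_polar
PTR	C	TRUE	other_polar
PTR	O	TRUE	acceptor
PTR	OXT	TRUE	acceptor
PTR	CB	FALSE	apolar
PTR	CG	FALSE	apolar
PTR	CD1	FALSE	apolar
PTR	CD2	FALSE	apolar
PTR	CE1	FALSE	apolar
PTR	CE2	FALSE	apolar
PTR	CZ	FALSE	other_polar
PTR	OH	FALSE	charged_negative
PTR	P	FALSE	other_polar
PTR	O1P	FALSE	charged_negative
PTR	O2P	FALSE	charged_negative
PTR	O3P	FALSE	charged_negative
PTR	OP1	FALSE	charged_negative
PTR	OP2	FALSE	charged_negative
PTR	OP3	FALSE	charged_negative
ACE	C	TRUE	other_polar
ACE	O	TRUE	acceptor
ACE	CH3	TRUE	apolar
NME	N	TRUE	donor
NME	CH3	TRUE	other_polar
NME	CA	TRUE	other_polar
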