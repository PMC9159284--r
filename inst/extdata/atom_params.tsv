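res_name	atom_name	radius	charge	atype
ALA	N	1.7	-0.3	N_don
ALA	CA	1.9	0	C_aliph
ALA	C	1.9	0.7	C_aliph
ALA	O	1.6	-0.4	O_acc
ALA	CB	1.9	0	C_aliph
GLY	N	1.7	-0.3	N_don
GLY	CA	1.9	0	C_aliph
GLY	C	1.9	0.7	C_aliph
GLY	O	1.6	-0.4	O_acc
VAL	N	1.7	-0.3	N_don
VAL	CA	1.9	0	C_aliph
VAL	C	1.9	0.7	C_aliph
VAL	O	1.6	-0.4	O_acc
VAL	CB	1.9	0	C_aliph
VAL	CG1	1.9	0	C_aliph
VAL	CG2	1.9	0	C_aliph
LEU	N	1.7	-0.3	N_don
LEU	CA	1.9	0	C_aliph
LEU	C	1.9	0.7	C_aliph
LEU	O	1.6	-0.4	O_acc
LEU	CB	1.9	0	C_aliph
LEU	CG	1.9	0	C_aliph
LEU	CD1	1.9	0	C_aliph
LEU	CD2	1.9	0	C_aliph
ILE	N	1.7	-0.3	N_don
ILE	CA	1.9	0	C_aliph
ILE	C	1.9	0.7	C_aliph
ILE	O	1.6	-0.4	O_acc
ILE	CB	1.9	0	C_aliph
ILE	CG1	1.9	0	C_aliph
ILE	CG2	1.9	0	C_aliph
ILE	CD1	1.9	0	C_aliph
MET	N	1.7	-0.3	N_don
MET	CA	1.9	0	C_aliph
MET	C	1.9	0.7	C_aliph
MET	O	1.6	-0.4	O_acc
MET	CB	1.9	0	C_aliph
MET	CG	1.9	0	C_aliph
MET	SD	2	0	S
MET	CE	1.9	0	C_aliph
PHE	N	1.7	-0.3	N_don
PHE	CA	1.9	0	C_aliph
PHE	C	1.9	0.7	C_aliph
PHE	O	1.6	-0.4	O_acc
PHE	CB	1.9	0	C_aliph
PHE	CG	1.9	0	C_arom
PHE	CD1	1.9	0	C_arom
PHE	CD2	1.9	0	C_arom
PHE	CE1	1.9	0	C_arom
PHE	CE2	1.9	0	C_arom
PHE	CZ	1.9	0	C_arom
TYR	N	1.7	-0.3	N_don
TYR	CA	1.9	0	C_aliph
TYR	C	1.9	0.7	C_aliph
TYR	O	1.6	-0.4	O_acc
TYR	CB	1.9	0	C_aliph
TYR	CG	1.9	0	C_arom
TYR	CD1	1.9	0	C_arom
TYR	CD2	1.9	0	C_arom
TYR	CE1	1.9	0	C_arom
TYR	CE2	1.9	0	C_arom
TYR	CZ	1.9	0.4	C_arom
TYR	OH	1.6	-0.4	O_acc
TRP	N	1.7	-0.3	N_don
TRP	CA	1.9	0	C_aliph
TRP	C	1.9	0.7	C_aliph
TRP	O	1.6	-0.4	O_acc
TRP	CB	1.9	0	C_aliph
TRP	CG	1.9	0	C_arom
TRP	CD1	1.9	0	C_arom
TRP	CD2	1.9	0	C_arom
TRP	NE1	1.7	-0.3	N_don
TRP	CE2	1.9	0.3	C_arom
TRP	CE3	1.9	0	C_arom
TRP	CZ2	1.9	0	C_arom
TRP	CZ3	1.9	0	C_arom
TRP	CH2	1.9	0	C_arom
SER	N	1.7	-0.3	N_don
SER	CA	1.9	0	C_aliph
SER	C	1.9	0.7	C_aliph
SER	O	1.6	-0.4	O_acc
SER	CB	1.9	0.3	C_aliph
SER	OG	1.6	-0.3	O_acc
THR	N	1.7	-0.3	N_don
THR	CA	1.9	0	C_aliph
THR	C	1.9	0.7	C_aliph
THR	O	1.6	-0.4	O_acc
THR	CB	1.9	0.3	C_aliph
THR	OG1	1.6	-0.3	O_acc
THR	CG2	1.9	0	C_aliph
CYS	N	1.7	-0.3	N_don
CYS	CA	1.9	0	C_aliph
CYS	C	1.9	0.7	C_aliph
CYS	O	1.6	-0.4	O_acc
CYS	CB	1.9	0.1	C_aliph
CYS	SG	2	-0.1	S
ASN	N	1.7	-0.3	N_don
ASN	CA	1.9	0	C_aliph
ASN	C	1.9	0.7	C_aliph
ASN	O	1.6	-0.4	O_acc
ASN	CB	1.9	0	C_aliph
ASN	CG	1.9	0.55	C_aliph
ASN	OD1	1.6	-0.4	O_acc
ASN	ND2	1.7	-0.15	N_don
GLN	N	1.7	-0.3	N_don
GLN	CA	1.9	0	C_aliph
GLN	C	1.9	0.7	C_aliph
GLN	O	1.6	-0.4	O_acc
GLN	CB	1.9	0	C_aliph
GLN	CG	1.9	0	C_aliph
GLN	CD	1.9	0.55	C_aliph
GLN	OE1	1.6	-0.4	O_acc
GLN	NE2	1.7	-0.15	N_don
ASP	N	1.7	-0.3	N_don
ASP	CA	1.9	0	C_aliph
ASP	C	1.9	0.7	C_aliph
ASP	O	1.6	-0.4	O_acc
ASP	CB	1.9	0	C_aliph
ASP	CG	1.9	0.3	C_aliph
ASP	OD1	1.6	-0.65	O_acc
ASP	OD2	1.6	-0.65	O_acc
GLU	N	1.7	-0.3	N_don
GLU	CA	1.9	0	C_aliph
GLU	C	1.9	0.7	C_aliph
GLU	O	1.6	-0.4	O_acc
GLU	CB	1.9	0	C_aliph
GLU	CG	1.9	0	C_aliph
GLU	CD	1.9	0.3	C_aliph
GLU	OE1	1.6	-0.65	O_acc
GLU	OE2	1.6	-0.65	O_acc
LYS	N	1.7	-0.3	N_don
LYS	CA	1.9	0	C_aliph
LYS	C	1.9	0.7	C_aliph
LYS	O	1.6	-0.4	O_acc
LYS	CB	1.9	0	C_aliph
LYS	CG	1.9	0	C_aliph
LYS	CD	1.9	0	C_aliph
LYS	CE	1.9	0.25	C_aliph
LYS	NZ	1.7	0.75	N_don
ARG	N	1.7	-0.3	N_don
ARG	CA	1.9	0	C_aliph
ARG	C	1.9	0.7	C_aliph
ARG	O	1.6	-0.4	O_acc
ARG	CB	1.9	0	C_aliph
ARG	CG	1.9	0	C_aliph
ARG	CD	1.9	0	C_aliph
ARG	NE	1.7	-0.1	N_don
ARG	CZ	1.9	0.5	C_aliph
ARG	NH1	1.7	0.3	N_don
ARG	NH2	1.7	0.3	N_don
HIS	N	1.7	-0.3	N_don
HIS	CA	1.9	0	C_aliph
HIS	C	1.9	0.7	C_aliph
HIS	O	1.6	-0.4	O_acc
HIS	CB	1.9	0	C_aliph
HIS	CG	1.9	0.1	C_arom
HIS	ND1	1.7	-0.3	N_don
HIS	CD2	1.9	0	C_arom
HIS	CE1	1.9	0.5	C_arom
HIS	NE2	1.7	-0.3	N_don
PRO	N	1.7	-0.3	other
PRO	CA	1.9	0	C_aliph
PRO	C	1.9	0.7	C_aliph
PRO	O	1.6	-0.4	O_acc
PRO	CB	1.9	0	C_aliph
PRO	CG	1.9	0	C_aliph
PRO	CD	1.9	0	C_aliph
.	C	1.9	0	other
.	N	1.7	0	other
.	O	1.6	0	other
.	S	2	0	other
.	P	2.1	0	other
.	X	1.8	0	other
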