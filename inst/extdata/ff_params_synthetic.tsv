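residue_name	atom_name	element	charge	epsilon	sigma
ACE	C	C	0.5972	0.086	3.4
ACE	CH3	C	-0.0293	0.086	3.4
ACE	O	O	-0.5679	0.21	2.96
ALA	C	C	0.5973	0.086	3.4
ALA	CA	C	0.0337	0.086	3.4
ALA	CB	C	0.0807	0.086	3.4
ALA	H	H	0.2719	0.0157	1.07
ALA	N	N	-0.4157	0.17	3.25
ALA	O	O	-0.5679	0.21	2.96
ARG	C	C	0.5973	0.086	3.4
ARG	CA	C	0.0337	0.086	3.4
ARG	CB	C	1.0807	0.086	3.4
ARG	H	H	0.2719	0.0157	1.07
ARG	N	N	-0.4157	0.17	3.25
ARG	O	O	-0.5679	0.21	2.96
ASN	C	C	0.5973	0.086	3.4
ASN	CA	C	0.0337	0.086	3.4
ASN	CB	C	0.0807	0.086	3.4
ASN	H	H	0.2719	0.0157	1.07
ASN	N	N	-0.4157	0.17	3.25
ASN	O	O	-0.5679	0.21	2.96
ASP	C	C	0.5973	0.086	3.4
ASP	CA	C	0.0337	0.086	3.4
ASP	CB	C	-0.9193	0.086	3.4
ASP	H	H	0.2719	0.0157	1.07
ASP	N	N	-0.4157	0.17	3.25
ASP	O	O	-0.5679	0.21	2.96
CYS	C	C	0.5973	0.086	3.4
CYS	CA	C	0.0337	0.086	3.4
CYS	CB	C	0.0807	0.086	3.4
CYS	H	H	0.2719	0.0157	1.07
CYS	N	N	-0.4157	0.17	3.25
CYS	O	O	-0.5679	0.21	2.96
GLN	C	C	0.5973	0.086	3.4
GLN	CA	C	0.0337	0.086	3.4
GLN	CB	C	0.0807	0.086	3.4
GLN	H	H	0.2719	0.0157	1.07
GLN	N	N	-0.4157	0.17	3.25
GLN	O	O	-0.5679	0.21	2.96
GLU	C	C	0.5973	0.086	3.4
GLU	CA	C	0.0337	0.086	3.4
GLU	CB	C	-0.9193	0.086	3.4
GLU	H	H	0.2719	0.0157	1.07
GLU	N	N	-0.4157	0.17	3.25
GLU	O	O	-0.5679	0.21	2.96
GLY	C	C	0.5973	0.086	3.4
GLY	CA	C	0.1144	0.086	3.4
GLY	H	H	0.2719	0.0157	1.07
GLY	N	N	-0.4157	0.17	3.25
GLY	O	O	-0.5679	0.21	2.96
HIS	C	C	0.5973	0.086	3.4
HIS	CA	C	0.0337	0.086	3.4
HIS	CB	C	0.0807	0.086	3.4
HIS	H	H	0.2719	0.0157	1.07
HIS	N	N	-0.4157	0.17	3.25
HIS	O	O	-0.5679	0.21	2.96
ILE	C	C	0.5973	0.086	3.4
ILE	CA	C	0.0337	0.086	3.4
ILE	CB	C	0.0807	0.086	3.4
ILE	CG	C	0	0.086	3.4
ILE	H	H	0.2719	0.0157	1.07
ILE	N	N	-0.4157	0.17	3.25
ILE	O	O	-0.5679	0.21	2.96
LEU	C	C	0.5973	0.086	3.4
LEU	CA	C	0.0337	0.086	3.4
LEU	CB	C	0.0807	0.086	3.4
LEU	CG	C	0	0.086	3.4
LEU	H	H	0.2719	0.0157	1.07
LEU	N	N	-0.4157	0.17	3.25
LEU	O	O	-0.5679	0.21	2.96
LYS	C	C	0.5973	0.086	3.4
LYS	CA	C	0.0337	0.086	3.4
LYS	CB	C	1.0807	0.086	3.4
LYS	H	H	0.2719	0.0157	1.07
LYS	N	N	-0.4157	0.17	3.25
LYS	O	O	-0.5679	0.21	2.96
MET	C	C	0.5973	0.086	3.4
MET	CA	C	0.0337	0.086	3.4
MET	CB	C	0.0807	0.086	3.4
MET	CG	C	0	0.086	3.4
MET	H	H	0.2719	0.0157	1.07
MET	N	N	-0.4157	0.17	3.25
MET	O	O	-0.5679	0.21	2.96
NME	CH3	C	0.1438	0.086	3.4
NME	H	H	0.2719	0.0157	1.07
NME	N	N	-0.4157	0.17	3.25
PHE	C	C	0.5973	0.086	3.4
PHE	CA	C	0.0337	0.086	3.4
PHE	CB	C	0.0807	0.086	3.4
PHE	CG	C	0	0.086	3.4
PHE	H	H	0.2719	0.0157	1.07
PHE	N	N	-0.4157	0.17	3.25
PHE	O	O	-0.5679	0.21	2.96
PRO	C	C	0.5973	0.086	3.4
PRO	CA	C	0.0337	0.086	3.4
PRO	CB	C	0.0807	0.086	3.4
PRO	N	N	-0.1438	0.17	3.25
PRO	O	O	-0.5679	0.21	2.96
SER	C	C	0.5973	0.086	3.4
SER	CA	C	0.0337	0.086	3.4
SER	CB	C	0.0807	0.086	3.4
SER	H	H	0.2719	0.0157	1.07
SER	N	N	-0.4157	0.17	3.25
SER	O	O	-0.5679	0.21	2.96
THR	C	C	0.5973	0.086	3.4
THR	CA	C	0.0337	0.086	3.4
THR	CB	C	0.0807	0.086	3.4
THR	H	H	0.2719	0.0157	1.07
THR	N	N	-0.4157	0.17	3.25
THR	O	O	-0.5679	0.21	2.96
TRP	C	C	0.5973	0.086	3.4
TRP	CA	C	0.0337	0.086	3.4
TRP	CB	C	0.0807	0.086	3.4
TRP	CG	C	0	0.086	3.4
TRP	H	H	0.2719	0.0157	1.07
TRP	N	N	-0.4157	0.17	3.25
TRP	O	O	-0.5679	0.21	2.96
TYR	C	C	0.5973	0.086	3.4
TYR	CA	C	0.0337	0.086	3.4
TYR	CB	C	0.0807	0.086	3.4
TYR	CG	C	0	0.086	3.4
TYR	H	H	0.2719	0.0157	1.07
TYR	N	N	-0.4157	0.17	3.25
TYR	O	O	-0.5679	0.21	2.96
VAL	C	C	0.5973	0.086	3.4
VAL	CA	C	0.0337	0.086	3.4
VAL	CB	C	0.0807	0.086	3.4
VAL	H	H	0.2719	0.0157	1.07
VAL	N	N	-0.4157	0.17	3.25
VAL	O	O	-0.5679	0.21	2.96
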