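# Characteristic side-chain atom per residue type, used by GDC-SC.
# One distal functional atom per non-glycine standard residue; edit and
# pass via characteristic_atom_table(path=) to change the convention.
resname	atom
ALA	CB
ARG	NH1
ASN	OD1
ASP	OD1
CYS	SG
GLN	OE1
GLU	OE1
HIS	NE2
ILE	CD1
LEU	CD1
LYS	NZ
MET	CE
PHE	CZ
PRO	CG
SER	OG
THR	OG1
TRP	CH2
TYR	OH
VAL	CG1
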