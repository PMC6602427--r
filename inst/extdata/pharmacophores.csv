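resid,atom,element,labels
ALA,N,N,donor
ALA,CA,C,hydrophobic
ALA,C,C,hydrophobic
ALA,O,O,acceptor
ALA,CB,C,hydrophobic
ARG,N,N,donor
ARG,CA,C,hydrophobic
ARG,C,C,hydrophobic
ARG,O,O,acceptor
ARG,CB,C,hydrophobic
ARG,CG,C,hydrophobic
ARG,CD,C,hydrophobic
ARG,NE,N,donor;positive
ARG,CZ,C,hydrophobic;positive
ARG,NH1,N,donor;positive
ARG,NH2,N,donor;positive
ASN,N,N,donor
ASN,CA,C,hydrophobic
ASN,C,C,hydrophobic
ASN,O,O,acceptor
ASN,CB,C,hydrophobic
ASN,CG,C,hydrophobic
ASN,OD1,O,acceptor
ASN,ND2,N,donor
ASP,N,N,donor
ASP,CA,C,hydrophobic
ASP,C,C,hydrophobic
ASP,O,O,acceptor
ASP,CB,C,hydrophobic
ASP,CG,C,hydrophobic;negative
ASP,OD1,O,acceptor;negative
ASP,OD2,O,acceptor;negative
CYS,N,N,donor
CYS,CA,C,hydrophobic
CYS,C,C,hydrophobic
CYS,O,O,acceptor
CYS,CB,C,hydrophobic
CYS,SG,S,donor;sulfur
GLN,N,N,donor
GLN,CA,C,hydrophobic
GLN,C,C,hydrophobic
GLN,O,O,acceptor
GLN,CB,C,hydrophobic
GLN,CG,C,hydrophobic
GLN,CD,C,hydrophobic
GLN,OE1,O,acceptor
GLN,NE2,N,donor
GLU,N,N,donor
GLU,CA,C,hydrophobic
GLU,C,C,hydrophobic
GLU,O,O,acceptor
GLU,CB,C,hydrophobic
GLU,CG,C,hydrophobic
GLU,CD,C,hydrophobic;negative
GLU,OE1,O,acceptor;negative
GLU,OE2,O,acceptor;negative
GLY,N,N,donor
GLY,CA,C,hydrophobic
GLY,C,C,hydrophobic
GLY,O,O,acceptor
HIS,N,N,donor
HIS,CA,C,hydrophobic
HIS,C,C,hydrophobic
HIS,O,O,acceptor
HIS,CB,C,hydrophobic
HIS,CG,C,aromatic;hydrophobic
HIS,ND1,N,acceptor;aromatic;donor;positive
HIS,CD2,C,aromatic;hydrophobic
HIS,CE1,C,aromatic;hydrophobic
HIS,NE2,N,acceptor;aromatic;donor;positive
ILE,N,N,donor
ILE,CA,C,hydrophobic
ILE,C,C,hydrophobic
ILE,O,O,acceptor
ILE,CB,C,hydrophobic
ILE,CG1,C,hydrophobic
ILE,CG2,C,hydrophobic
ILE,CD1,C,hydrophobic
LEU,N,N,donor
LEU,CA,C,hydrophobic
LEU,C,C,hydrophobic
LEU,O,O,acceptor
LEU,CB,C,hydrophobic
LEU,CG,C,hydrophobic
LEU,CD1,C,hydrophobic
LEU,CD2,C,hydrophobic
LYS,N,N,donor
LYS,CA,C,hydrophobic
LYS,C,C,hydrophobic
LYS,O,O,acceptor
LYS,CB,C,hydrophobic
LYS,CG,C,hydrophobic
LYS,CD,C,hydrophobic
LYS,CE,C,hydrophobic
LYS,NZ,N,donor;positive
MET,N,N,donor
MET,CA,C,hydrophobic
MET,C,C,hydrophobic
MET,O,O,acceptor
MET,CB,C,hydrophobic
MET,CG,C,hydrophobic
MET,SD,S,sulfur
MET,CE,C,hydrophobic
PHE,N,N,donor
PHE,CA,C,hydrophobic
PHE,C,C,hydrophobic
PHE,O,O,acceptor
PHE,CB,C,hydrophobic
PHE,CG,C,aromatic;hydrophobic
PHE,CD1,C,aromatic;hydrophobic
PHE,CD2,C,aromatic;hydrophobic
PHE,CE1,C,aromatic;hydrophobic
PHE,CE2,C,aromatic;hydrophobic
PHE,CZ,C,aromatic;hydrophobic
PRO,N,N,neutral
PRO,CA,C,hydrophobic
PRO,C,C,hydrophobic
PRO,O,O,acceptor
PRO,CB,C,hydrophobic
PRO,CG,C,hydrophobic
PRO,CD,C,hydrophobic
SER,N,N,donor
SER,CA,C,hydrophobic
SER,C,C,hydrophobic
SER,O,O,acceptor
SER,CB,C,hydrophobic
SER,OG,O,acceptor;donor
THR,N,N,donor
THR,CA,C,hydrophobic
THR,C,C,hydrophobic
THR,O,O,acceptor
THR,CB,C,hydrophobic
THR,OG1,O,acceptor;donor
THR,CG2,C,hydrophobic
TRP,N,N,donor
TRP,CA,C,hydrophobic
TRP,C,C,hydrophobic
TRP,O,O,acceptor
TRP,CB,C,hydrophobic
TRP,CG,C,aromatic;hydrophobic
TRP,CD1,C,aromatic;hydrophobic
TRP,CD2,C,aromatic;hydrophobic
TRP,NE1,N,aromatic;donor
TRP,CE2,C,aromatic;hydrophobic
TRP,CE3,C,aromatic;hydrophobic
TRP,CZ2,C,aromatic;hydrophobic
TRP,CZ3,C,aromatic;hydrophobic
TRP,CH2,C,aromatic;hydrophobic
TYR,N,N,donor
TYR,CA,C,hydrophobic
TYR,C,C,hydrophobic
TYR,O,O,acceptor
TYR,CB,C,hydrophobic
TYR,CG,C,aromatic;hydrophobic
TYR,CD1,C,aromatic;hydrophobic
TYR,CD2,C,aromatic;hydrophobic
TYR,CE1,C,aromatic;hydrophobic
TYR,CE2,C,aromatic;hydrophobic
TYR,CZ,C,aromatic;hydrophobic
TYR,OH,O,acceptor;donor
VAL,N,N,donor
VAL,CA,C,hydrophobic
VAL,C,C,hydrophobic
VAL,O,O,acceptor
VAL,CB,C,hydrophobic
VAL,CG1,C,hydrophobic
VAL,CG2,C,hydrophobic
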