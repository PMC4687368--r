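res	phi	psi	chi1	chi2	chi3	chi4	prob
VAL	-60	-40	-65	NA	NA	NA	0.5
VAL	-60	-40	180	NA	NA	NA	0.3
VAL	-60	-40	62	NA	NA	NA	0.15
VAL	-120	120	-65	NA	NA	NA	0.35
VAL	-120	120	180	NA	NA	NA	0.45
VAL	-120	120	62	NA	NA	NA	0.15
VAL	180	180	-65	NA	NA	NA	0.4
VAL	180	180	180	NA	NA	NA	0.35
VAL	180	180	62	NA	NA	NA	0.2
LEU	-60	-40	-65	175	NA	NA	0.5
LEU	-60	-40	180	175	NA	NA	0.3
LEU	-60	-40	62	175	NA	NA	0.15
LEU	-120	120	-65	175	NA	NA	0.35
LEU	-120	120	180	175	NA	NA	0.45
LEU	-120	120	62	175	NA	NA	0.15
LEU	180	180	-65	175	NA	NA	0.4
LEU	180	180	180	175	NA	NA	0.35
LEU	180	180	62	175	NA	NA	0.2
ILE	-60	-40	-65	170	NA	NA	0.5
ILE	-60	-40	180	170	NA	NA	0.3
ILE	-60	-40	62	170	NA	NA	0.15
ILE	-120	120	-65	170	NA	NA	0.35
ILE	-120	120	180	170	NA	NA	0.45
ILE	-120	120	62	170	NA	NA	0.15
ILE	180	180	-65	170	NA	NA	0.4
ILE	180	180	180	170	NA	NA	0.35
ILE	180	180	62	170	NA	NA	0.2
PHE	-60	-40	-65	90	NA	NA	0.5
PHE	-60	-40	180	90	NA	NA	0.3
PHE	-60	-40	62	90	NA	NA	0.15
PHE	-120	120	-65	90	NA	NA	0.35
PHE	-120	120	180	90	NA	NA	0.45
PHE	-120	120	62	90	NA	NA	0.15
PHE	180	180	-65	90	NA	NA	0.4
PHE	180	180	180	90	NA	NA	0.35
PHE	180	180	62	90	NA	NA	0.2
TYR	-60	-40	-65	90	NA	NA	0.5
TYR	-60	-40	180	90	NA	NA	0.3
TYR	-60	-40	62	90	NA	NA	0.15
TYR	-120	120	-65	90	NA	NA	0.35
TYR	-120	120	180	90	NA	NA	0.45
TYR	-120	120	62	90	NA	NA	0.15
TYR	180	180	-65	90	NA	NA	0.4
TYR	180	180	180	90	NA	NA	0.35
TYR	180	180	62	90	NA	NA	0.2
TRP	-60	-40	-65	95	NA	NA	0.5
TRP	-60	-40	180	95	NA	NA	0.3
TRP	-60	-40	62	95	NA	NA	0.15
TRP	-120	120	-65	95	NA	NA	0.35
TRP	-120	120	180	95	NA	NA	0.45
TRP	-120	120	62	95	NA	NA	0.15
TRP	180	180	-65	95	NA	NA	0.4
TRP	180	180	180	95	NA	NA	0.35
TRP	180	180	62	95	NA	NA	0.2
HIS	-60	-40	-65	-75	NA	NA	0.5
HIS	-60	-40	180	-75	NA	NA	0.3
HIS	-60	-40	62	-75	NA	NA	0.15
HIS	-120	120	-65	-75	NA	NA	0.35
HIS	-120	120	180	-75	NA	NA	0.45
HIS	-120	120	62	-75	NA	NA	0.15
HIS	180	180	-65	-75	NA	NA	0.4
HIS	180	180	180	-75	NA	NA	0.35
HIS	180	180	62	-75	NA	NA	0.2
SER	-60	-40	-65	NA	NA	NA	0.5
SER	-60	-40	180	NA	NA	NA	0.3
SER	-60	-40	62	NA	NA	NA	0.15
SER	-120	120	-65	NA	NA	NA	0.35
SER	-120	120	180	NA	NA	NA	0.45
SER	-120	120	62	NA	NA	NA	0.15
SER	180	180	-65	NA	NA	NA	0.4
SER	180	180	180	NA	NA	NA	0.35
SER	180	180	62	NA	NA	NA	0.2
THR	-60	-40	-65	NA	NA	NA	0.5
THR	-60	-40	180	NA	NA	NA	0.3
THR	-60	-40	62	NA	NA	NA	0.15
THR	-120	120	-65	NA	NA	NA	0.35
THR	-120	120	180	NA	NA	NA	0.45
THR	-120	120	62	NA	NA	NA	0.15
THR	180	180	-65	NA	NA	NA	0.4
THR	180	180	180	NA	NA	NA	0.35
THR	180	180	62	NA	NA	NA	0.2
CYS	-60	-40	-65	NA	NA	NA	0.5
CYS	-60	-40	180	NA	NA	NA	0.3
CYS	-60	-40	62	NA	NA	NA	0.15
CYS	-120	120	-65	NA	NA	NA	0.35
CYS	-120	120	180	NA	NA	NA	0.45
CYS	-120	120	62	NA	NA	NA	0.15
CYS	180	180	-65	NA	NA	NA	0.4
CYS	180	180	180	NA	NA	NA	0.35
CYS	180	180	62	NA	NA	NA	0.2
MET	-60	-40	-65	180	180	NA	0.5
MET	-60	-40	180	180	180	NA	0.3
MET	-60	-40	62	180	180	NA	0.15
MET	-120	120	-65	180	180	NA	0.35
MET	-120	120	180	180	180	NA	0.45
MET	-120	120	62	180	180	NA	0.15
MET	180	180	-65	180	180	NA	0.4
MET	180	180	180	180	180	NA	0.35
MET	180	180	62	180	180	NA	0.2
ASP	-60	-40	-65	-20	NA	NA	0.5
ASP	-60	-40	180	-20	NA	NA	0.3
ASP	-60	-40	62	-20	NA	NA	0.15
ASP	-120	120	-65	-20	NA	NA	0.35
ASP	-120	120	180	-20	NA	NA	0.45
ASP	-120	120	62	-20	NA	NA	0.15
ASP	180	180	-65	-20	NA	NA	0.4
ASP	180	180	180	-20	NA	NA	0.35
ASP	180	180	62	-20	NA	NA	0.2
ASN	-60	-40	-65	-30	NA	NA	0.5
ASN	-60	-40	180	-30	NA	NA	0.3
ASN	-60	-40	62	-30	NA	NA	0.15
ASN	-120	120	-65	-30	NA	NA	0.35
ASN	-120	120	180	-30	NA	NA	0.45
ASN	-120	120	62	-30	NA	NA	0.15
ASN	180	180	-65	-30	NA	NA	0.4
ASN	180	180	180	-30	NA	NA	0.35
ASN	180	180	62	-30	NA	NA	0.2
GLU	-60	-40	-65	180	180	NA	0.5
GLU	-60	-40	180	180	180	NA	0.3
GLU	-60	-40	62	180	180	NA	0.15
GLU	-120	120	-65	180	180	NA	0.35
GLU	-120	120	180	180	180	NA	0.45
GLU	-120	120	62	180	180	NA	0.15
GLU	180	180	-65	180	180	NA	0.4
GLU	180	180	180	180	180	NA	0.35
GLU	180	180	62	180	180	NA	0.2
GLN	-60	-40	-65	180	180	NA	0.5
GLN	-60	-40	180	180	180	NA	0.3
GLN	-60	-40	62	180	180	NA	0.15
GLN	-120	120	-65	180	180	NA	0.35
GLN	-120	120	180	180	180	NA	0.45
GLN	-120	120	62	180	180	NA	0.15
GLN	180	180	-65	180	180	NA	0.4
GLN	180	180	180	180	180	NA	0.35
GLN	180	180	62	180	180	NA	0.2
LYS	-60	-40	-65	180	180	180	0.5
LYS	-60	-40	180	180	180	180	0.3
LYS	-60	-40	62	180	180	180	0.15
LYS	-120	120	-65	180	180	180	0.35
LYS	-120	120	180	180	180	180	0.45
LYS	-120	120	62	180	180	180	0.15
LYS	180	180	-65	180	180	180	0.4
LYS	180	180	180	180	180	180	0.35
LYS	180	180	62	180	180	180	0.2
ARG	-60	-40	-65	180	180	180	0.5
ARG	-60	-40	180	180	180	180	0.3
ARG	-60	-40	62	180	180	180	0.15
ARG	-120	120	-65	180	180	180	0.35
ARG	-120	120	180	180	180	180	0.45
ARG	-120	120	62	180	180	180	0.15
ARG	180	180	-65	180	180	180	0.4
ARG	180	180	180	180	180	180	0.35
ARG	180	180	62	180	180	180	0.2
ORN	-60	-40	-65	180	180	NA	0.5
ORN	-60	-40	180	180	180	NA	0.3
ORN	-60	-40	62	180	180	NA	0.15
ORN	-120	120	-65	180	180	NA	0.35
ORN	-120	120	180	180	180	NA	0.45
ORN	-120	120	62	180	180	NA	0.15
ORN	180	180	-65	180	180	NA	0.4
ORN	180	180	180	180	180	NA	0.35
ORN	180	180	62	180	180	NA	0.2
SEP	-60	-40	-65	180	180	NA	0.5
SEP	-60	-40	180	180	180	NA	0.3
SEP	-60	-40	62	180	180	NA	0.15
SEP	-120	120	-65	180	180	NA	0.35
SEP	-120	120	180	180	180	NA	0.45
SEP	-120	120	62	180	180	NA	0.15
SEP	180	180	-65	180	180	NA	0.4
SEP	180	180	180	180	180	NA	0.35
SEP	180	180	62	180	180	NA	0.2
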