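data_chiscan_parameters
#
# Default force-field snapshot shipped with chiscan.
#
# Covalent radii and their uncertainties follow the Pyykko self-consistent
# single-bond values. Lennard-Jones well depths (kcal/mol) and rmin/2 (A)
# are Amber-style per-element classes; partial charges are the package's
# own united-atom (heavy-atom-only) assignment with correct per-residue
# net charges. Chemically equivalent atoms of symmetric groups (ASP
# OD1/OD2, GLU OE1/OE2, PHE/TYR CD1/CD2 and CE1/CE2) carry identical
# parameters so that a 180-degree flip of the symmetric chi angle leaves
# the energy unchanged. Torsion barriers V (kcal/mol) use periodicity
# n = 3 about sp3-sp3 bonds and n = 2 about bonds with partial double-bond
# or aromatic character (keys "COMP:k" select chi_k of one residue type and
# take precedence over element-pair keys; "default" is the last resort).
#
loop_
_chiscan_element.symbol
_chiscan_element.covalent_radius
_chiscan_element.covalent_radius_error
_chiscan_element.vdw_radius
_chiscan_element.lj_epsilon
_chiscan_element.lj_rmin_half
H  0.32 0.03 1.20 0.0157 0.6000
C  0.75 0.03 1.70 0.1094 1.9080
N  0.71 0.03 1.55 0.1700 1.8240
O  0.63 0.03 1.52 0.2100 1.6612
S  1.03 0.03 1.80 0.2500 2.0000
SE 1.16 0.04 1.90 0.2900 2.1000
#
_chiscan_weights.w1 1.0
_chiscan_weights.w2 1.0
_chiscan_weights.w3 1.0
_chiscan_weights.w4 1.0
_chiscan_cutoff.start 2.5
_chiscan_cutoff.end   5.0
_chiscan_bond.tolerance    0.4
_chiscan_bond.min_distance 0.5
_chiscan_hbond.epsilon 2.0
_chiscan_hbond.rmin    2.9
#
loop_
_chiscan_torsion.key
_chiscan_torsion.v
_chiscan_torsion.n
_chiscan_torsion.gamma
default 1.4 3 0
C:C     1.4 3 0
C:N     1.0 3 0
C:S     1.0 3 0
ASP:2   0.5 2 180
GLU:3   0.5 2 180
ASN:2   0.5 2 180
GLN:3   0.5 2 180
PHE:2   0.8 2 180
TYR:2   0.8 2 180
HIS:2   0.8 2 180
TRP:2   0.8 2 180
ARG:4   1.0 2 180
#
# Partial charges (elementary charge units). comp_id "*" matches any
# residue type and is overridden by residue-specific rows.
loop_
_chiscan_charge.comp_id
_chiscan_charge.atom_id
_chiscan_charge.value
*   N    -0.40
*   CA    0.20
*   C     0.55
*   O    -0.55
*   OXT  -0.55
*   CB    0.00
ALA CB    0.00
SER CB    0.45
SER OG   -0.45
THR CB    0.35
THR OG1  -0.45
THR CG2   0.10
CYS CB    0.15
CYS SG   -0.15
VAL CG1   0.00
VAL CG2   0.00
LEU CG    0.00
LEU CD1   0.00
LEU CD2   0.00
ILE CG1   0.00
ILE CG2   0.00
ILE CD1   0.00
MET CG    0.12
MET SD   -0.24
MET CE    0.12
PHE CG    0.00
PHE CD1   0.00
PHE CD2   0.00
PHE CE1   0.00
PHE CE2   0.00
PHE CZ    0.00
TYR CG    0.00
TYR CD1   0.00
TYR CD2   0.00
TYR CE1   0.00
TYR CE2   0.00
TYR CZ    0.30
TYR OH   -0.30
TRP CG    0.00
TRP CD1   0.10
TRP NE1  -0.30
TRP CE2   0.20
TRP CD2   0.00
TRP CE3   0.00
TRP CZ2   0.00
TRP CZ3   0.00
TRP CH2   0.00
HIS CG    0.10
HIS ND1  -0.40
HIS CD2   0.10
HIS CE1   0.30
HIS NE2  -0.10
ASP CB   -0.10
ASP CG    0.60
ASP OD1  -0.75
ASP OD2  -0.75
GLU CG   -0.10
GLU CD    0.60
GLU OE1  -0.75
GLU OE2  -0.75
ASN CG    0.55
ASN OD1  -0.55
ASN ND2   0.00
GLN CG    0.00
GLN CD    0.55
GLN OE1  -0.55
GLN NE2   0.00
LYS CG    0.00
LYS CD    0.00
LYS CE    0.25
LYS NZ    0.75
ARG CG    0.00
ARG CD    0.10
ARG NE   -0.10
ARG CZ    0.60
ARG NH1   0.20
ARG NH2   0.20
PRO CG    0.00
PRO CD    0.10
#
# Hydrogen-bond roles of heavy atoms (12-10 well applied to
# donor-acceptor pairs; "both" can act as either partner).
loop_
_chiscan_hbond_atom.comp_id
_chiscan_hbond_atom.atom_id
_chiscan_hbond_atom.role
*   N    donor
*   O    acceptor
*   OXT  acceptor
SER OG   both
THR OG1  both
TYR OH   both
CYS SG   acceptor
MET SD   acceptor
ASP OD1  acceptor
ASP OD2  acceptor
GLU OE1  acceptor
GLU OE2  acceptor
ASN OD1  acceptor
ASN ND2  donor
GLN OE1  acceptor
GLN NE2  donor
HIS ND1  both
HIS NE2  both
TRP NE1  donor
LYS NZ   donor
ARG NE   donor
ARG NH1  donor
ARG NH2  donor
#
# Side-chain chi definitions (IUPAC atom quadruples; rotation about the
# bond between atoms 2 and 3).
loop_
_chiscan_chi.comp_id
_chiscan_chi.index
_chiscan_chi.atom_1
_chiscan_chi.atom_2
_chiscan_chi.atom_3
_chiscan_chi.atom_4
SER 1 N  CA CB OG
CYS 1 N  CA CB SG
THR 1 N  CA CB OG1
VAL 1 N  CA CB CG1
ASP 1 N  CA CB CG
ASP 2 CA CB CG OD1
ASN 1 N  CA CB CG
ASN 2 CA CB CG OD1
LEU 1 N  CA CB CG
LEU 2 CA CB CG CD1
ILE 1 N  CA CB CG1
ILE 2 CA CB CG1 CD1
HIS 1 N  CA CB CG
HIS 2 CA CB CG ND1
PHE 1 N  CA CB CG
PHE 2 CA CB CG CD1
TYR 1 N  CA CB CG
TYR 2 CA CB CG CD1
TRP 1 N  CA CB CG
TRP 2 CA CB CG CD1
MET 1 N  CA CB CG
MET 2 CA CB CG SD
MET 3 CB CG SD CE
GLU 1 N  CA CB CG
GLU 2 CA CB CG CD
GLU 3 CB CG CD OE1
GLN 1 N  CA CB CG
GLN 2 CA CB CG CD
GLN 3 CB CG CD OE1
LYS 1 N  CA CB CG
LYS 2 CA CB CG CD
LYS 3 CB CG CD CE
LYS 4 CG CD CE NZ
ARG 1 N  CA CB CG
ARG 2 CA CB CG CD
ARG 3 CB CG CD NE
ARG 4 CG CD NE CZ
#
# Incremental build order: chi_group k means the atom moves with chi_k
# (and all more proximal chi angles) and is placed at scan depth k.
loop_
_chiscan_build.comp_id
_chiscan_build.atom_id
_chiscan_build.chi_group
SER OG  1
CYS SG  1
THR OG1 1
THR CG2 1
VAL CG1 1
VAL CG2 1
ASP CG  1
ASP OD1 2
ASP OD2 2
ASN CG  1
ASN OD1 2
ASN ND2 2
LEU CG  1
LEU CD1 2
LEU CD2 2
ILE CG1 1
ILE CG2 1
ILE CD1 2
HIS CG  1
HIS ND1 2
HIS CD2 2
HIS CE1 2
HIS NE2 2
PHE CG  1
PHE CD1 2
PHE CD2 2
PHE CE1 2
PHE CE2 2
PHE CZ  2
TYR CG  1
TYR CD1 2
TYR CD2 2
TYR CE1 2
TYR CE2 2
TYR CZ  2
TYR OH  2
TRP CG  1
TRP CD1 2
TRP CD2 2
TRP NE1 2
TRP CE2 2
TRP CE3 2
TRP CZ2 2
TRP CZ3 2
TRP CH2 2
MET CG  1
MET SD  2
MET CE  3
GLU CG  1
GLU CD  2
GLU OE1 3
GLU OE2 3
GLN CG  1
GLN CD  2
GLN OE1 3
GLN NE2 3
LYS CG  1
LYS CD  2
LYS CE  3
LYS NZ  4
ARG CG  1
ARG CD  2
ARG NE  3
ARG CZ  4
ARG NH1 4
ARG NH2 4
#
# Explicit intra-residue covalent bonds (checked before the geometric
# cell-grid fallback; inter-residue bonds are always geometric).
loop_
_chiscan_bond_list.comp_id
_chiscan_bond_list.atom_1
_chiscan_bond_list.atom_2
*   N   CA
*   CA  C
*   C   O
*   CA  CB
SER CB  OG
CYS CB  SG
THR CB  OG1
THR CB  CG2
VAL CB  CG1
VAL CB  CG2
ASP CB  CG
ASP CG  OD1
ASP CG  OD2
ASN CB  CG
ASN CG  OD1
ASN CG  ND2
LEU CB  CG
LEU CG  CD1
LEU CG  CD2
ILE CB  CG1
ILE CB  CG2
ILE CG1 CD1
HIS CB  CG
HIS CG  ND1
HIS CG  CD2
HIS ND1 CE1
HIS CE1 NE2
HIS NE2 CD2
PHE CB  CG
PHE CG  CD1
PHE CG  CD2
PHE CD1 CE1
PHE CD2 CE2
PHE CE1 CZ
PHE CE2 CZ
TYR CB  CG
TYR CG  CD1
TYR CG  CD2
TYR CD1 CE1
TYR CD2 CE2
TYR CE1 CZ
TYR CE2 CZ
TYR CZ  OH
TRP CB  CG
TRP CG  CD1
TRP CG  CD2
TRP CD1 NE1
TRP NE1 CE2
TRP CE2 CD2
TRP CD2 CE3
TRP CE3 CZ3
TRP CZ3 CH2
TRP CH2 CZ2
TRP CZ2 CE2
MET CB  CG
MET CG  SD
MET SD  CE
GLU CB  CG
GLU CG  CD
GLU CD  OE1
GLU CD  OE2
GLN CB  CG
GLN CG  CD
GLN CD  OE1
GLN CD  NE2
LYS CB  CG
LYS CG  CD
LYS CD  CE
LYS CE  NZ
ARG CB  CG
ARG CG  CD
ARG CD  NE
ARG NE  CZ
ARG CZ  NH1
ARG CZ  NH2
PRO CB  CG
PRO CG  CD
PRO CD  N
#
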