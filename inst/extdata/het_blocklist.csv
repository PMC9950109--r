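het_code,category
GLC,monosaccharide
BGC,monosaccharide
GAL,monosaccharide
GLA,monosaccharide
MAN,monosaccharide
BMA,monosaccharide
FUC,monosaccharide
FUL,monosaccharide
XYS,monosaccharide
XYP,monosaccharide
RIB,monosaccharide
FRU,monosaccharide
ARA,monosaccharide
RAM,monosaccharide
SIA,monosaccharide
NAG,monosaccharide
NDG,monosaccharide
GCU,monosaccharide
GCS,monosaccharide
A2G,monosaccharide
HEM,prosthetic_group
HEC,prosthetic_group
HEA,prosthetic_group
FAD,prosthetic_group
FMN,prosthetic_group
NAD,prosthetic_group
NAI,prosthetic_group
NAP,prosthetic_group
NDP,prosthetic_group
PLP,prosthetic_group
PQQ,prosthetic_group
B12,prosthetic_group
CLA,prosthetic_group
BCL,prosthetic_group
SF4,prosthetic_group
FES,prosthetic_group
F3S,prosthetic_group
TPP,prosthetic_group
TDP,prosthetic_group
COA,prosthetic_group
GOL,crystallization_additive
EDO,crystallization_additive
PEG,crystallization_additive
PGE,crystallization_additive
PG4,crystallization_additive
P6G,crystallization_additive
1PE,crystallization_additive
MPD,crystallization_additive
DMS,crystallization_additive
ACT,crystallization_additive
ACY,crystallization_additive
FMT,crystallization_additive
BME,crystallization_additive
DTT,crystallization_additive
TRS,crystallization_additive
EPE,crystallization_additive
MES,crystallization_additive
MRD,crystallization_additive
PGO,crystallization_additive
POL,crystallization_additive
IPA,crystallization_additive
ETX,crystallization_additive
BTB,crystallization_additive
CIT,crystallization_additive
TLA,crystallization_additive
TAR,crystallization_additive
MLI,crystallization_additive
SCN,crystallization_additive
AZI,crystallization_additive
NO3,polyatomic_ion
SO4,polyatomic_ion
SO3,polyatomic_ion
PO4,polyatomic_ion
PO3,polyatomic_ion
2HP,polyatomic_ion
VO4,polyatomic_ion
WO4,polyatomic_ion
MOO,polyatomic_ion
CO3,polyatomic_ion
BO3,polyatomic_ion
SEK,polyatomic_ion
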