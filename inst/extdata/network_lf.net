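# Carbon-transition network for proliferating lung fibroblasts.
# 48 chemical reactions (glycolysis, pentose phosphate pathway, TCA cycle,
# anaplerosis, serine metabolism, biomass synthesis) plus three pyruvate
# mixing pseudo-reactions and a lumped unlabeled acetyl-CoA source.
#
# Dialect: `ID: coef*MET (atoms) + ... ->|<-> products`, lowercase letters
# map carbons one-to-one across the arrow; `<->` marks reversible (net +
# exchange) reactions; `0*` reactants contribute label but no mass.
# Suffixes: .x extracellular, .c cytosol, .m mitochondria, .ms mixed pool.
# Atom maps reconstructed from standard biochemistry; citrate synthase /
# isocitrate dehydrogenase / 2-oxoglutarate dehydrogenase follow the usual
# convention in which the acetyl carbons become AKG C4-C5 and the first two
# CO2 released derive from oxaloacetate.

@unbalanced CO2 FAO biomass lipid PYR.fix
@symmetric SUC FUM
@pseudo cPYR mPYR sPYR FAO

@pathway Transport
GLUT: GLC.x (abcdef) -> GLC (abcdef)
PYRR: PYR.x (abc) -> PYR.c (abc)
MCT: LAC (abc) <-> LAC.x (abc)
ALAR: ALA (abc) -> ALA.x (abc)
GLNR: GLN.x (abcde) -> GLN (abcde)
GLUR: GLU (abcde) <-> GLU.x (abcde)
ASPR: ASP (abcd) -> ASP.x (abcd)
SERR: SER.x (abc) -> SER (abc)
CYSR: CYX.x (abcdef) -> CYS (abc) + CYS (def)
GLYR: GLY (ab) -> GLY.x (ab)

@pathway Glycolysis
HK: GLC (abcdef) -> G6P (abcdef)
PGI: G6P (abcdef) <-> F6P (abcdef)
PFK: F6P (abcdef) -> FBP (abcdef)
ALDO: FBP (abcdef) <-> DHAP (cba) + GAP (def)
TPI: DHAP (abc) <-> GAP (abc)
GAPDH: GAP (abc) <-> PG3 (abc)
ENO: PG3 (abc) -> PEP (abc)
PK: PEP (abc) -> PYR.c (abc)
LDH: PYR.c (abc) <-> LAC (abc)
GPT1: PYR.c (abc) <-> ALA (abc)
GPT2: PYR.m (abc) <-> ALA (abc)

@pathway PentosePhosphate
G6PD: G6P (abcdef) -> P5P (bcdef) + CO2 (a)
TK1: P5P (abcde) + P5P (fghij) <-> S7P (abfghij) + GAP (cde)
TA: S7P (abcdefg) + GAP (hij) <-> F6P (abchij) + E4P (defg)
TK2: P5P (abcde) + E4P (fghi) <-> F6P (abfghi) + GAP (cde)

@pathway Anaplerosis
PYRT: PYR.c (abc) -> PYR.m (abc)
PC: PYR.m (abc) + CO2 (d) -> OAC (abcd)
PEPCK: OAC (abcd) -> PEP (abc) + CO2 (d)
ME2: MAL (abcd) -> PYR.m (abc) + CO2 (d)
ME1: MAL (abcd) -> PYR.c (abc) + CO2 (d)
FAO: FAO (ab) -> AcCoA.m (ab)
GLDH: GLU (abcde) <-> AKG (abcde)
GLS: GLN (abcde) <-> GLU (abcde)

@pathway TCA
PDH: PYR.m (abc) -> AcCoA.m (bc) + CO2 (a)
CS: OAC (abcd) + AcCoA.m (ef) -> CIT (dcbfea)
IDH: CIT (abcdef) <-> AKG (abcde) + CO2 (f)
OGDH: AKG (abcde) -> SUC (bcde) + CO2 (a)
SDH: SUC (abcd) <-> FUM (abcd)
FH: FUM (abcd) <-> MAL (abcd)
MDH: MAL (abcd) <-> OAC (abcd)
GOT: OAC (abcd) <-> ASP (abcd)

@pathway AminoAcid
PST: PG3 (abc) -> SER (abc)
SHT: SER (abc) <-> GLY (ab) + MEETHF (c)
CYST: SER (abc) <-> CYS (abc)
SD: SER (abc) -> PYR.c (abc)
GLYS: CO2 (a) + MEETHF (b) -> GLY (ab)

@pathway Biomass
BIOMASS: 1216*AcCoA.c + 295.6*ALA + 232.4*ASP + 114.7*CO2 + 71.43*CYS + 57.14*DHAP + 142.4*G6P + 158.6*GLN + 190.1*GLU + 324.2*GLY + 125.6*MEETHF + 114.7*P5P + 217.2*SER -> biomass
ACL: CIT (abcdef) -> AcCoA.c (ed) + MAL (fcba)
LIPS: AcCoA.c (ab) -> lipid (ab)

@pathway Mixing
cPYR: 0*PYR.c (abc) -> PYR.ms (abc)
mPYR: 0*PYR.m (abc) -> PYR.ms (abc)
sPYR: PYR.ms (abc) -> PYR.fix (abc)
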