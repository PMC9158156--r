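# Dementia-related genes and risk loci screened per family.
# Assembled from literature-standard gene sets for Alzheimer's disease,
# frontotemporal dementia / ALS, prion disease and Parkinson's disease.
# AD: Mendelian and risk genes
APP
PSEN1
PSEN2
APOE
SORL1
TREM2
ABCA7
ABI3
ADAM10
AKAP9
BIN1
CLU
CR1
CD33
FERMT2
MADD
PICALM
PLCG2
PLD3
UNC5C
# FTD / ALS
GRN
MAPT
C9orf72
CHMP2B
CHCHD10
FUS
OPTN
SQSTM1
TARDBP
TBK1
UBQLN2
VCP
# prion disease
PRNP
# other dementias / overlapping neurodegeneration
CSF1R
ITM2B
NOTCH3
TYROBP
# Parkinson's disease
GBA
LRRK2
PARK7
PINK1
PRKN
SNCA
VPS35
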