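TP53
EGFR
KRAS
NRAS
HRAS
BRAF
MYC
MYCN
PTEN
RB1
BRCA1
BRCA2
ATM
ATR
CHEK1
CHEK2
CDKN2A
CDKN1A
CDKN1B
CCND1
CCNE1
CDK4
CDK6
CDK2
E2F1
MDM2
MDM4
PIK3CA
PIK3R1
AKT1
AKT2
AKT3
MTOR
TSC1
TSC2
STK11
NF1
NF2
APC
CTNNB1
GSK3B
AXIN1
SMAD2
SMAD3
SMAD4
TGFB1
TGFBR1
TGFBR2
NOTCH1
NOTCH2
NOTCH3
DLL1
JAG1
HES1
WNT1
WNT3A
FZD1
LRP5
LRP6
SHH
GLI1
GLI2
PTCH1
SMO
FGFR1
FGFR2
FGFR3
FGFR4
FGF2
VEGFA
VEGFB
KDR
FLT1
FLT3
KIT
PDGFRA
PDGFRB
MET
ALK
ROS1
RET
NTRK1
NTRK2
NTRK3
ERBB2
ERBB3
ERBB4
IGF1R
INSR
IRS1
IRS2
JAK1
JAK2
JAK3
TYK2
STAT1
STAT2
STAT3
STAT4
STAT5A
STAT5B
STAT6
SOCS1
SOCS3
IL2
IL4
IL6
IL10
IL13
IL15
IL17A
IL1B
IL2RA
IL6R
IL7R
TNF
TNFRSF1A
TNFRSF1B
FAS
FASLG
TRADD
TRAF2
TRAF6
RIPK1
CASP3
CASP7
CASP8
CASP9
CASP1
BAX
BAK1
BCL2
BCL2L1
MCL1
BID
BAD
BIK
PMAIP1
BBC3
APAF1
CYCS
XIAP
BIRC2
BIRC3
BIRC5
NFKB1
NFKB2
RELA
RELB
REL
NFKBIA
IKBKB
IKBKG
CHUK
MAP2K1
MAP2K2
MAP2K3
MAP2K4
MAP2K6
MAP2K7
MAPK1
MAPK3
MAPK8
MAPK9
MAPK10
MAPK11
MAPK12
MAPK13
MAPK14
MAP3K1
MAP3K5
MAP3K7
RAF1
ARAF
SRC
FYN
LCK
LYN
HCK
FGR
BLK
YES1
ABL1
ABL2
BTK
SYK
ZAP70
PLCG1
PLCG2
PRKCA
PRKCB
PRKCD
PRKCE
PRKCG
PRKCH
PRKCI
PRKCZ
PRKACA
PRKAR1A
CAMK2A
CAMK2B
CAMK4
CALM1
CALM2
CALM3
PPP1CA
PPP2CA
PPP3CA
PPP3CB
PTPN1
PTPN6
PTPN11
PTPRC
DUSP1
DUSP4
DUSP6
CREB1
ATF1
ATF2
ATF4
JUN
JUNB
JUND
FOS
FOSB
FOSL1
FOSL2
ELK1
ETS1
ETS2
SP1
SP3
EGR1
KLF2
KLF4
KLF6
GATA1
GATA2
GATA3
GATA4
GATA6
TBX5
TBX21
FOXA1
FOXA2
FOXO1
FOXO3
FOXP3
SOX2
SOX9
SOX10
POU5F1
NANOG
LIN28A
PAX5
PAX6
RUNX1
RUNX2
RUNX3
CEBPA
CEBPB
SPI1
IRF1
IRF3
IRF4
IRF7
IRF8
HIF1A
EPAS1
ARNT
VHL
EP300
CREBBP
KAT2B
HDAC1
HDAC2
HDAC3
HDAC6
SIRT1
SIRT3
SIRT6
DNMT1
DNMT3A
DNMT3B
TET1
TET2
TET3
EZH2
SUZ12
EED
KMT2A
KMT2C
KMT2D
SETD2
KDM6A
KDM6B
KDM5A
ARID1A
ARID1B
ARID2
SMARCA2
SMARCA4
SMARCB1
PBRM1
BRD4
CTCF
RAD21
SMC1A
SMC3
STAG2
CDH1
CDH2
CDH5
VIM
FN1
SNAI1
SNAI2
TWIST1
ZEB1
ZEB2
MMP2
MMP9
MMP14
TIMP1
TIMP2
ITGA5
ITGAV
ITGB1
ITGB3
ILK
PTK2
PXN
TLN1
VCL
ACTB
ACTG1
ACTA2
MYH9
MYH11
MYL9
TPM1
TUBB
TUBA1A
TUBA1B
KRT5
KRT6A
KRT8
KRT14
KRT17
KRT18
KRT19
KRT7
LMNA
LMNB1
NES
GFAP
DES
ALB
AFP
TTR
APOA1
APOB
APOE
LDLR
SREBF1
SREBF2
HMGCR
FASN
ACACA
SCD
PPARA
PPARD
PPARG
PPARGC1A
NR3C1
ESR1
ESR2
PGR
AR
THRA
THRB
RARA
RARB
RXRA
VDR
NR1H3
NR1H4
AHR
NFE2L2
KEAP1
HMOX1
NQO1
GCLC
GSTP1
SOD1
SOD2
CAT
GPX1
GPX4
TXN
PRDX1
G6PD
TP63
TP73
NKX2-1
NKX2-5
NKX3-1
TTF1
SFTPC
SFTPB
SCGB1A1
MUC1
MUC5AC
MUC16
CEACAM5
EPCAM
MKI67
PCNA
TOP2A
AURKA
AURKB
PLK1
BUB1
BUB1B
MAD2L1
CDC20
CDC25A
CDC25C
WEE1
CDK1
CCNB1
CCNA2
ORC1
MCM2
MCM3
MCM7
CDT1
CDC6
GINS1
POLA1
POLD1
POLE
PRIM1
RRM1
RRM2
TYMS
DHFR
TK1
LIG1
FEN1
XRCC1
XRCC5
XRCC6
PRKDC
RAD50
MRE11
NBN
RAD51
RAD52
BLM
WRN
RECQL4
FANCA
FANCD2
PALB2
MLH1
MSH2
MSH6
PMS2
MGMT
ERCC1
ERCC2
XPA
XPC
DDB2
POLH
REV3L
H2AX
MACROH2A1
HSPA1A
HSPA5
HSPA8
HSP90AA1
HSP90AB1
HSPB1
DNAJB1
BAG3
STUB1
UBB
UBC
UBA52
PSMB5
PSMB8
PSMA1
VCP
SQSTM1
MAP1LC3B
ATG5
ATG7
ATG12
BECN1
ULK1
LAMP1
LAMP2
CTSB
CTSD
CTSL
TFEB
RAB5A
RAB7A
RAB11A
EEA1
CAV1
CAV2
CLTC
DNM2
SNX9
VPS35
SEC61A1
SRP54
CANX
CALR
PDIA3
ERN1
EIF2AK3
ATF6
XBP1
DDIT3
EIF2S1
EIF4E
EIF4EBP1
RPS6
RPS6KB1
RPS6KA1
EEF2
EEF2K
RPL13A
GAPDH
PGK1
PKM
LDHA
LDHB
HK1
HK2
PFKL
PFKM
ALDOA
ENO1
PDHA1
PDK1
CS
IDH1
IDH2
IDH3A
SDHA
SDHB
FH
MDH2
OGDH
SUCLA2
ACO2
GLS
GLUD1
GOT1
GOT2
ASNS
PHGDH
PSAT1
SHMT1
SHMT2
MTHFR
SLC2A1
SLC2A4
SLC7A11
SLC7A5
SLC1A5
SLC16A1
SLC25A1
CPT1A
CPT2
ACADM
ACADVL
HADHA
ECHS1
ACOX1
PPOX
ALAS1
FECH
HBB
HBA1
HBA2
EPO
EPOR
TFRC
TF
FTH1
FTL
SLC40A1
HAMP
CP
CD4
CD8A
CD8B
CD3D
CD3E
CD3G
CD247
CD19
MS4A1
CD79A
CD79B
CD14
CD68
CD163
ITGAM
ITGAX
FCGR1A
FCGR3A
NCAM1
KLRD1
NKG7
GNLY
PRF1
GZMA
GZMB
GZMK
CD38
HLA-A
HLA-B
HLA-C
HLA-DRA
HLA-DRB1
HLA-DQA1
HLA-DPB1
B2M
TAP1
TAP2
CIITA
CD80
CD86
CD28
CTLA4
PDCD1
CD274
PDCD1LG2
LAG3
HAVCR2
TIGIT
ICOS
TNFRSF9
TNFRSF4
CD40
CD40LG
CD27
CD70
IL21
IFNG
IFNA1
IFNB1
IFNGR1
IFNAR1
MX1
OAS1
ISG15
IFIT1
IFIT3
IRF9
CXCL8
CXCL9
CXCL10
CXCL12
CXCR3
CXCR4
CCL2
CCL3
CCL4
CCL5
CCR2
CCR5
CCR7
SELL
SELP
ICAM1
VCAM1
PECAM1
CDH17
LYZ
MPO
ELANE
CTSG
DEFA1
CAMP
S100A8
S100A9
S100A4
ANXA1
ANXA2
ANXA5
LGALS1
LGALS3
LGALS9
CLEC4C
CLEC9A
XCR1
BATF3
ZBTB46
FLT3LG
CSF1
CSF1R
CSF2
CSF2RA
CSF3
CSF3R
KITLG
MPL
THPO
GATA5
TAL1
LMO2
GFI1
GFI1B
KLF1
ZFPM1
VWF
F8
F2
F3
F5
F7
F10
PLG
SERPINE1
SERPINA1
PLAT
PLAU
PLAUR
THBD
PROC
PROS1
FGA
FGB
FGG
ITGA2B
GP1BA
P2RY12
TBXA2R
PTGS1
PTGS2
ALOX5
ALOX15
LTA4H
CYP1A1
CYP1A2
CYP2D6
CYP2C9
CYP2C19
CYP3A4
CYP2E1
UGT1A1
NAT2
TPMT
GSTM1
GSTT1
SULT1A1
ABCB1
ABCC1
ABCC2
ABCG2
SLCO1B1
ADH1B
ALDH2
ALDH1A1
AKR1C3
EPHX1
FMO3
MAOA
MAOB
COMT
TH
DDC
DBH
SLC6A3
SLC6A4
DRD1
DRD2
DRD4
HTR1A
HTR2A
CHRM1
CHRNA7
GRIN1
GRIN2A
GRIN2B
GRIA1
GRM5
GABRA1
GABBR1
GAD1
GAD2
SLC17A7
SYP
SYN1
SNAP25
VAMP2
STX1A
SYT1
DLG4
SHANK3
NLGN3
NRXN1
MECP2
FMR1
HTT
SNCA
PARK7
PINK1
PRKN
LRRK2
GBA
MAPT
APP
PSEN1
PSEN2
BACE1
TREM2
GRN
C9orf72
SOD3
TARDBP
FUS
SMN1
SMN2
DMD
UTRN
MYOD1
MYOG
MYF5
PAX3
PAX7
MSTN
IGF1
IGF2
GH1
GHR
INS
IGFBP3
LEP
LEPR
ADIPOQ
RETN
GCG
GIP
GLP1R
DPP4
SLC5A2
KCNJ11
ABCC8
GCK
HNF1A
HNF4A
PDX1
NEUROD1
ISL1
MAFA
NKX6-1
SST
PPY
TTN
MYH7
MYH6
MYBPC3
TNNT2
TNNI3
TPM2
ACTC1
MYL2
MYL3
CSRP3
LDB3
PLN
RYR2
CACNA1C
SCN5A
KCNQ1
KCNH2
KCNE1
GJA1
NPPA
NPPB
ACE
AGT
AGTR1
REN
EDN1
EDNRA
NOS1
NOS2
NOS3
GUCY1A1
PDE5A
ADRB1
ADRB2
ADRA1A
GNAS
GNAQ
GNA11
GNB1
ARRB1
ARRB2
GRK2
RGS4
RHOA
RAC1
CDC42
RHOB
RHOC
ROCK1
ROCK2
PAK1
PAK2
WASF2
WASL
ARPC2
ARPC3
CFL1
LIMK1
SSH1
GSN
PFN1
TMSB4X
EZR
RDX
MSN
MERTK
AXL
TYRO3
GAS6
EFNA1
EFNB2
EPHA2
EPHB4
ROBO1
SLIT2
DCC
NTN1
UNC5B
SEMA3A
PLXNA1
NRP1
NRP2
L1CAM
NCAM2
CNTN1
CHL1
TNC
SPARC
SPP1
BGLAP
COL1A1
COL1A2
COL2A1
COL3A1
COL4A1
COL4A5
COL5A1
COL6A1
COL11A1
COL17A1
LAMA1
LAMB1
LAMC1
NID1
HSPG2
ACAN
VCAN
DCN
LUM
FMOD
ELN
FBN1
FBLN5
LOX
LOXL2
P4HA1
PLOD1
SERPINH1
MMP1
MMP3
MMP7
MMP13
ADAM10
ADAM17
ADAMTS1
ADAMTS5
CTSK
ACP5
TNFSF11
TNFRSF11A
TNFRSF11B
SOST
DKK1
WNT5A
WNT10B
BMP2
BMP4
BMP7
BMPR1A
BMPR2
NOG
GREM1
CHRD
ACVR1
ACVR2A
INHBA
INHA
FST
GDF15
AMH
CGA
CGB3
LHB
FSHB
TSHB
PRL
POMC
CRH
CRHR1
AVP
AVPR2
OXT
OXTR
TRH
TRHR
GNRH1
GNRHR
KISS1
KISS1R
MC4R
AGRP
NPY
NPY1R
PYY
GHRL
GHSR
HCRT
HCRTR1
PMCH
TAC1
TACR1
PENK
PDYN
OPRM1
OPRD1
OPRK1
CNR1
CNR2
FAAH
MGLL
TRPV1
TRPA1
TRPM8
PIEZO1
PIEZO2
SCN9A
SCN10A
KCNA1
KCND3
KCNMA1
HCN1
HCN4
CLCN1
CFTR
AQP1
AQP2
AQP4
SLC12A1
SLC12A3
SCNN1A
ATP1A1
ATP1B1
ATP2A2
ATP2B1
ATP7A
ATP7B
SLC26A4
SLC4A1
CA2
CA9
CA12
UMOD
NPHS1
NPHS2
WT1
PKD1
PKD2
PKHD1
COL4A3
COL4A4
ACE2
SLC34A1
KL
FGF23
CYP27B1
CYP24A1
PTH
PTH1R
CASR
TRPV5
S100B
CALB1
CALB2
PVALB
SLC8A1
CACNA1A
CACNB2
RYR1
TNNC1
MYLK
CNN1
TAGLN
SMTN
CALD1
LMOD1
PDLIM3
SYNPO2
FLNA
FLNC
SGCA
SGCB
DAG1
DTNA
SNTA1
CAPN3
TRIM32
FKRP
POMT1
LARGE1
EMD
SYNE1
SUN1
TMPO
TOR1A
PLEC
DST
KRT1
KRT2
KRT4
KRT10
KRT13
KRT15
KRT16
KRT20
IVL
LOR
FLG
TGM1
SPINK5
KLK5
KLK7
CDSN
DSG1
DSG3
DSC2
DSP
PKP1
PKP2
JUP
PERP
CLDN1
CLDN4
CLDN7
OCLN
TJP1
TJP2
F11R
CGN
MARVELD2
CRB3
PARD3
PARD6A
SCRIB
DLG1
LLGL1
AMOT
YAP1
WWTR1
LATS1
LATS2
STK3
STK4
SAV1
MOB1A
TEAD1
TEAD4
AJUBA
FAT1
FAT4
DCHS1
CELSR1
VANGL2
PRICKLE1
DVL1
DVL2
ROR2
RYK
PTK7
EOMES
PRDM1
BCL6
BACH2
ID2
ID3
TCF7
LEF1
TCF3
TCF12
HES5
HEY1
HEY2
RBPJ
MAML1
ADAM19
PSENEN
NCSTN
APH1A
DTX1
NUMB
LFNG
MFNG
RFNG
POFUT1
EOGT
EGFL7
DLL3
DLL4
JAG2
MIB1
NEURL1
GBX2
OTX2
EN1
EN2
FGF8
FGF17
WNT8A
SIX3
HESX1
LHX2
RAX
VSX2
CRX
NRL
RHO
OPN1SW
GNAT1
PDE6B
CNGA1
RPE65
RLBP1
BEST1
TYR
TYRP1
DCT
MITF
PMEL
MLANA
EDNRB
ASIP
MC1R
OCA2
SLC45A2
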