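# Cleft-palate gene panel (n = 322): genes whose disruption causes cleft palate
# in mouse (MGI-derived) or human (OMIM-derived). Source tags are heuristic,
# assigned by symbol typography (title-case -> mouse, upper-case -> human);
# the transcribed list carries no per-gene source attribution.
symbol	source	ortholog_symbol
Acvr1	mouse	
Lhx8	mouse	
Cask	mouse	
ATR	human	
FLNB	human	
MEGF10	human	
RPL11	human	
Akap8	mouse	
Luzp1	mouse	
Cdkn1c	mouse	
ATRX	human	
FLVCR2	human	
MID1	human	
RPL5	human	
Ap2b1	mouse	
Meox2	mouse	
Chd7	mouse	
B3GALTL	human	
FRAS1	human	
MKS1	human	
RPS17	human	
Apaf1	mouse	
Mmp14	mouse	
Col2a1	mouse	
B3GAT3	human	
FREM2	human	
MLL2	human	
RPS19	human	
Bmp7	mouse	
Mmp16	mouse	
Dhcr7	mouse	
B9D1	human	
FTO	human	
MSX2	human	
RPS7	human	
Bnc2	mouse	
Mn1	mouse	
Dlx5	mouse	
BCOR	human	
G6PC3	human	
MTHFR	human	
SALL4	human	
Boc	mouse	
Mnt	mouse	
Efnb1	mouse	
BMP2	human	
GABRB3	human	
MUTYH	human	
SC5DL	human	
Cacna1s	mouse	
Msc	mouse	
Eya1	mouse	
BMP4	human	
GATA6	human	
MYH3	human	
SCARF2	human	
Cdon	mouse	
Ncoa6	mouse	
Fgf10	mouse	
BMPER	human	
GCMB	human	
NBS1	human	
SEMA3E	human	
Chrd	mouse	
Ncor2	mouse	
Fgfr1	mouse	
BRAF	human	
GDF1	human	
NEB	human	
SF3B4	human	
Chuk	mouse	
Osr2	mouse	
Fgfr2	mouse	
BRIP1	human	
GDF6	human	
NEK1	human	
SHFM3	human	
Crebbp	mouse	
Pax9	mouse	
Flna	mouse	
BUB1B	human	
GJA1	human	
NIPBL	human	
SLC26A2	human	
Crk	mouse	
Pbx1	mouse	
Foxc2	mouse	
CANT1	human	
GJB2	human	
NKX2-5	human	
SLC35D1	human	
Ctgf	mouse	
Pcgf2	mouse	
Foxe1	mouse	
CASR	human	
GLI3	human	
NKX2-6	human	
SMOC1	human	
Ctnnb1	mouse	
Pdgfc	mouse	
Gad1	mouse	
CDC6	human	
GPC3	human	
NSD1	human	
SMS	human	
Dlg1	mouse	
Pdgfra	mouse	
Hoxa2	mouse	
CDH1	human	
GUSB	human	
OFC4	human	
SOX2	human	
Dlx1	mouse	
Pds5a	mouse	
Impad1	mouse	
CFC1	human	
H19	human	
OFD1	human	
SPECC1L	human	
Dlx2	mouse	
Pds5b	mouse	
Inpp5e	mouse	
CHRNA1	human	
HCA1	human	
ORC1	human	
SPINT2	human	
Ednrb	mouse	
Phc1	mouse	
Irf6	mouse	
CHRND	human	
HPGD	human	
OTX2	human	
SPTLC1	human	
Ext1	mouse	
Phc2	mouse	
Kcnj2	mouse	
CHRNG	human	
HVEC	human	
PAX3	human	
SRY	human	
Fgf18	mouse	
Pkdcc	mouse	
Msx1	mouse	
CHST14	human	
HYAL1	human	
PAX8	human	
STRA6	human	
Fgf9	mouse	
Prdm16	mouse	
Pitx1	mouse	
CHSY1	human	
HYLS1	human	
PEX7	human	
TAB2	human	
Fign	mouse	
Prrx2	mouse	
Prrx1	mouse	
COL11A1	human	
ICK	human	
PHF8	human	
TBX15	human	
Foxf2	mouse	
Ptprf	mouse	
Ror2	mouse	
COL11A2	human	
IL1B	human	
PIGL	human	
TBX19	human	
Foxg1	mouse	
Ptprs	mouse	
Runx2	mouse	
COL9A2	human	
IL1RN	human	
PIGV	human	
TBX4	human	
Fst	mouse	
Rad23b	mouse	
Satb2	mouse	
COLEC11	human	
IMAGE	human	
PIK3CA	human	
TBX5	human	
Fuz	mouse	
Rfng	mouse	
Shh	mouse	
COMT	human	
IRF1	human	
PLCB4	human	
TCTN2	human	
Fzd1	mouse	
Rspo2	mouse	
Six3	mouse	
CRLF1	human	
KAL1	human	
POLR1C	human	
TGFβ1	human	
Fzd2	mouse	
Ryk	mouse	
Sox9	mouse	
DGCR2	human	
KAT6B	human	
POLR1D	human	
TGFβR1	human	
Gab1	mouse	
Ryr1	mouse	
Sumo1	mouse	
DHCR24	human	
KCNJ13	human	
POMT1	human	
TMCO1	human	
Gli2	mouse	
Sfn	mouse	
Tbx1	mouse	
DHODH	human	
KIAA1289	human	
POMT2	human	
TMEM216	human	
Gpr124	mouse	
Shox2	mouse	
Tbx22	mouse	
DIS3L2	human	
KIF22	human	
PORCN	human	
TMEM67	human	
Grb2	mouse	
Sim2	mouse	
Tcof1	mouse	
DOK7	human	
KIF7	human	
PQBP1	human	
TRIM37	human	
Gsk3b	mouse	
Skor2	mouse	
Tfap2a	mouse	
DXS423E	human	
KLF6	human	
PROKR2	human	
TRPS2	human	
Hand2	mouse	
Slc32a1	mouse	
TGFβ3	human	
DYNC2H1	human	
KRAS	human	
PTCH1	human	
TWIST1	human	
Hoxa1	mouse	
Snai1	mouse	
TGFβr2	mouse	
EFTUD2	human	
L1CAM	human	
PTEN	human	
UBB	human	
Hs2st1	mouse	
Snai2	mouse	
Tp63	mouse	
EPHB2	human	
LMNA	human	
PTH	human	
VCAN	human	
Ift172	mouse	
Sox11	mouse	
ABCD3	human	
ERBB2	human	
LMX1B	human	
PTPN11	human	
WDR65	human	
Ift88	mouse	
Sox5	mouse	
ACAN	human	
ERCC5	human	
LRP4	human	
PXMP3	human	
WNT3	human	
Inhba	mouse	
Tbx10	mouse	
ACTB	human	
ESCO2	human	
MADH3	human	
RAI1	human	
WNT5A	human	
Inhbb	mouse	
Tbx2	mouse	
ALX1	human	
FAM123B	human	
MAP2K1	human	
RAPSN	human	
WNT7A	human	
Itgav	mouse	
Tbx3	mouse	
ALX3	human	
FAM20C	human	
MAP2K2	human	
RB1	human	
WT1	human	
Itgb8	mouse	
TGFβ2	human	
ARHGAP31	human	
FBN1	human	
MASP1	human	
RBM10	human	
ZEB2	human	
Jag2	mouse	
Tshz1	mouse	
ARID1B	human	
FGD1	human	
MBTPS2	human	
RECQL4	human	
ZIC2	human	
Jmjd6	mouse	
Wdr19	mouse	
ARNT	human	
FGF8	human	
MCOPS8	human	
RIPK4	human	
ZIC3	human	
Kif3a	mouse	
Zeb1	mouse	
ASXL1	human	
FGFR3	human	
MED12	human	
RPGRIP1L	human	
ZMPSTE24	human	
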