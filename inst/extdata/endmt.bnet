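targets, factors
AP1, WNT5b | SMAD2
CTNNB, WNT5b | WNT7a
DLL4, DLL4
ETS1, VEGFR2 | FGF2 | ZEB2 | AP1
FGF2, FGF2
FLI1, FLI1 | GATA2 | HIF1a
GATA2, FLI1 | GATA2 | VEGFR2
HIF1a, HIF1a
LEF1, LEF1 | NRARP | SMAD2 | NFkB | CTNNB
NFkB, PDGF_AB
NOTCH, DLL4 & !NRARP
NRARP, NOTCH
NRP1, VEGFA & (ETS1 | GATA2) & !NOTCH
PDGF_AB, PDGF_AB
SMAD1, TGFBR & !SMAD6
SMAD2, TGFBR & !SMAD6 & NRP1
SMAD6, FLI1 & GATA2 & (NOTCH | SMAD1)
SNAI1, (HIF1a | STAT3 | CTNNB | AP1 | NFkB | SMAD2) & (NOTCH | CTNNB) & !TWIST1 & !SNAI1 & !SNAI2
SNAI2, !(SNAI1 & GATA2) & (SMAD2 | SNAI2 | TWIST1 | LEF1 | NOTCH)
STAT3, VEGFR2
TGFB, TGFB
TGFBR, TGFB & !FGF2
TWIST1, CTNNB | HIF1a
VEGFA, !WNT5b & !TGFBR & (STAT3 | HIF1a) | VEGFA
VEGFR2, VEGFA & !SNAI1 & !NOTCH & (FLI1 | GATA2 | ETS1)
WNT5b, WNT5b
WNT7a, WNT7a
ZEB1, SNAI2 | CTNNB | LEF1
ZEB2, HIF1a | ETS1 | SMAD2 | AP1 | SNAI1
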