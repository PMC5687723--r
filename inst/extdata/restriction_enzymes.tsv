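AatII	GACGT^C
AccI	GT^MKAC
AclI	AA^CGTT
AcuI	CTGAAG(16/14)
AfeI	AGC^GCT
AflII	C^TTAAG
AflIII	A^CRYGT
AgeI	A^CCGGT
AhdI	GACNNN^NNGTC
AluI	AG^CT
AlwNI	CAGNNN^CTG
ApaI	GGGCC^C
ApaLI	G^TGCAC
ApoI	R^AATTY
AscI	GG^CGCGCC
AseI	AT^TAAT
AvaI	C^YCGRG
AvaII	G^GWCC
AvrII	C^CTAGG
BaeI	ACNNNNGTAYC	double
BamHI	G^GATCC
BanI	G^GYRCC
BanII	GRGCY^C
BbsI	GAAGAC(2/6)
BcgI	CGANNNNNNTGC	double
BciVI	GTATCC(12/10)
BclI	T^GATCA
BfaI	C^TAG
BglI	GCCNNNN^NGGC
BglII	A^GATCT
BlpI	GC^TNAGC
BmrI	ACTGGG(5/4)
BmtI	GCTAG^C
BpmI	CTGGAG(16/14)
BpuEI	CTTGAG(16/14)
BsaAI	YAC^GTR
BsaBI	GATNN^NNATC
BsaHI	GR^CGYC
BsaI	GGTCTC(1/5)
BsaJI	C^CNNGG
BsgI	GTGCAG(16/14)
BsiEI	CGRY^CG
BsiWI	C^GTACG
BslI	CCNNNNN^NNGG
BsmBI	CGTCTC(1/5)
BsoBI	C^YCGRG
Bsp1286I	GDGCH^C
BspEI	T^CCGGA
BspHI	T^CATGA
BspQI	GCTCTTC(1/4)
BsrDI	GCAATG(2/0)
BsrGI	T^GTACA
BssHII	G^CGCGC
BstBI	TT^CGAA
BstEII	G^GTNACC
BstNI	CC^WGG
BstUI	CG^CG
BstXI	CCANNNNN^NTGG
BstYI	R^GATCY
BstZ17I	GTA^TAC
BtgI	C^CRYGG
BtsI	GCAGTG(2/0)
Cac8I	GCN^NGC
ClaI	AT^CGAT
DdeI	C^TNAG
DpnII	^GATC
DraI	TTT^AAA
DraIII	CACNNN^GTG
DrdI	GACNNNN^NNGTC
EaeI	Y^GGCCR
EagI	C^GGCCG
EarI	CTCTTC(1/4)
EciI	GGCGGA(11/9)
EcoNI	CCTNN^NNNAGG
EcoO109I	RG^GNCCY
EcoRI	G^AATTC
EcoRV	GAT^ATC
FokI	GGATG(9/13)
FseI	GGCCGG^CC
FspI	TGC^GCA
HaeII	RGCGC^Y
HaeIII	GG^CC
HgaI	GACGC(5/10)
HhaI	GCG^C
HincII	GTY^RAC
HindIII	A^AGCTT
HinfI	G^ANTC
HpaI	GTT^AAC
HpaII	C^CGG
HphI	GGTGA(8/7)
Hpy166II	GTN^NAC
Hpy188I	TCN^GA
HpyCH4IV	A^CGT
HpyCH4V	TG^CA
KasI	G^GCGCC
KpnI	GGTAC^C
MboII	GAAGA(8/7)
MfeI	C^AATTG
MluI	A^CGCGT
MlyI	GAGTC(5/5)
MnlI	CCTC(7/6)
MscI	TGG^CCA
MseI	T^TAA
MslI	CAYNN^NNRTG
MspA1I	CMG^CKG
MwoI	GCNNNNN^NNGC
NaeI	GCC^GGC
NarI	GG^CGCC
Nb.BsrDI	GCAATG	nicking
Nb.BtsI	GCAGTG	nicking
NcoI	C^CATGG
NdeI	CA^TATG
NgoMIV	G^CCGGC
NheI	G^CTAGC
NlaIII	CATG^
NlaIV	GGN^NCC
NotI	GC^GGCCGC
NruI	TCG^CGA
NsiI	ATGCA^T
NspI	RCATG^Y
Nt.BspQI	GCTCTTC	nicking
Nt.BstNBI	GAGTC	nicking
PacI	TTAAT^TAA
PciI	A^CATGT
PflMI	CCANNNN^NTGG
PleI	GAGTC(4/5)
PmeI	GTTT^AAAC
PmlI	CAC^GTG
PpuMI	RG^GWCCY
PsiI	TTA^TAA
PspOMI	G^GGCCC
PstI	CTGCA^G
PvuI	CGAT^CG
PvuII	CAG^CTG
RsaI	GT^AC
SacI	GAGCT^C
SacII	CCGC^GG
SalI	G^TCGAC
Sau3AI	^GATC
Sau96I	G^GNCC
SbfI	CCTGCA^GG
ScaI	AGT^ACT
ScrFI	CC^NGG
SfcI	C^TRYAG
SfiI	GGCCNNNN^NGGCC
SfoI	GGC^GCC
SgrAI	CR^CCGGYG
SmaI	CCC^GGG
SmlI	C^TYRAG
SnaBI	TAC^GTA
SpeI	A^CTAGT
SphI	GCATG^C
SspI	AAT^ATT
StuI	AGG^CCT
StyI	C^CWWGG
SwaI	ATTT^AAAT
TaqI	T^CGA
TfiI	G^AWTC
TseI	G^CWGC
Tsp509I	^AATT
XbaI	T^CTAGA
XcmI	CCANNNNN^NNNNTGG
XhoI	C^TCGAG
XmaI	C^CCGGG
XmnI	GAANN^NNTTC
ZraI	GAC^GTC
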