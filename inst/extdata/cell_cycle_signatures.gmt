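G1S	curated G1/S-transition markers (Whitfield-style phase list, reconstructed from canonical human cell-cycle genes)	CCNE1	CCNE2	CDC6	CDC45	CDT1	E2F1	MCM2	MCM3	MCM4	MCM5	MCM6	MCM7	PCNA	SLBP	GINS2	CHAF1A	CHAF1B	DHFR	ORC1	RRM1	UHRF1	WDR76
S	curated S-phase markers (Whitfield-style phase list, reconstructed from canonical human cell-cycle genes)	RRM2	TYMS	FEN1	HELLS	CLSPN	ATAD2	BRIP1	CDC7	DSCC1	EXO1	GMNN	POLA1	POLE2	PRIM1	RAD51AP1	RFC4	RPA2	UNG	USP1	MSH2
G2	curated G2-phase markers (Whitfield-style phase list, reconstructed from canonical human cell-cycle genes)	CCNA2	TOP2A	CDK1	NDC80	NUSAP1	TACC3	SMC4	KIF11	KIF23	CKAP2	FOXM1	G2E3	GTSE1	HMMR	MELK	TTK	CENPF	AURKB	BIRC5	CKS2
G2M	curated G2/M-transition markers (Whitfield-style phase list, reconstructed from canonical human cell-cycle genes)	CCNB1	CCNB2	CDC20	CDC25C	PLK1	AURKA	BUB1	BUB1B	CENPA	CENPE	DLGAP5	ECT2	KIF20A	KIF2C	NEK2	PSRC1	TPX2	UBE2C	ANLN	CDCA3
MG1	curated M/G1 markers (Whitfield-style phase list, reconstructed from canonical human cell-cycle genes)	CCND1	ANAPC1	CDKN3	PTTG1	RAD21	VEGFC	CTCF	GAS2L3	KIF5B	MTF2	PRPF4B	TROAP	HJURP	PSMD11	DCTN6	DKC1	LBR	NUF2	TUBB4B	CDC42EP1
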