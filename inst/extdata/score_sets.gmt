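BASAL_UP	basal urothelial markers	KRT6A	KRT14	KRT16	KRT5	CD44	CXCL8	IL1R2
LUMINAL	luminal urothelial markers	UPK3B	UPK1A	UPK2	FOXA1	PAX8	GATA3	PPARG	TFAP2B	PIK3C2G
EMT_UP	epithelial-mesenchymal transition, mesenchymal arm	VIM	ZEB1	ZEB2	SNAI1	SNAI2	TWIST1	CDH2	TGFB1
EMT_DOWN	epithelial-mesenchymal transition, epithelial arm	CDH1	CLDN1	TJP1	DSP	OCLN
OXPHOS	oxidative phosphorylation complexes I-V	NDUFA1	NDUFB5	NDUFS2	SDHA	SDHB	UQCRC1	UQCRC2	CYC1	COX5A	COX7B	ATP5F1A	ATP5F1B	ATP5MC1
TCA	citric acid cycle enzymes	CS	ACO2	IDH3A	OGDH	SUCLA2	SDHB	FH	MDH2
GLYCOLYSIS	glycolysis and anaerobic switch	LDHA	HK2	PFKM	ALDOA	ENO1	PKM	SLC2A1
IMMUNE	immune infiltration	PTPRC	CD3D	CD3E	CD8A	GZMB	PRF1	CD74
T_EXHAUSTION	T-cell exhaustion	PDCD1	CTLA4	LAG3	HAVCR2	TIGIT	TOX
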