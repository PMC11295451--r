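level	cell_type	gene	source
main	epithelial	KRT8	screened
main	epithelial	KRT18	screened
main	epithelial	KRT15	screened
main	epithelial	KRT17	screened
main	epithelial	KRT19	screened
main	epithelial	KRT7	screened
main	epithelial	AGR2	screened
main	epithelial	CLDN4	screened
main	stromal	CLDN5	screened
main	stromal	SELE	screened
main	stromal	VWF	screened
main	stromal	ENG	screened
main	stromal	IGFBP7	screened
main	stromal	IFI27	screened
main	stromal	EMCN	screened
main	stromal	CD200	screened
main	stromal	C7	screened
main	stromal	VIM	screened
main	stromal	PTGDS	screened
main	stromal	GJA4	screened
main	stromal	RGS5	screened
main	stromal	MT1A	screened
main	stromal	COL1A2	screened
main	stromal	MYH11	screened
main	stromal	ACTG2	screened
main	stromal	BGN	screened
main	stromal	THY1	screened
main	stromal	PDGFRB	screened
main	stromal	NRP1	screened
main	stromal	ANGPT2	screened
main	stromal	COL3A1	screened
main	stromal	COL4A1	screened
main	stromal	COL4A2	screened
main	stromal	COL18A1	screened
main	epithelial	AR	literature
main	epithelial	TEAD1	literature
main	epithelial	IER3	literature
main	epithelial	EGR1	literature
main	epithelial	DST	literature
main	epithelial	S100A6	literature
main	epithelial	ID1	literature
main	epithelial	SERPINB1	literature
main	epithelial	PLA2G2A	literature
main	epithelial	CHGB	literature
main	epithelial	RARRES1	literature
main	epithelial	EZH2	literature
main	epithelial	SIAH2	literature
main	stromal	C1S	literature
main	stromal	FBLN1	literature
fine	luminal	AR	literature
fine	luminal	DPP4	literature
fine	luminal	KLK2	literature
fine	luminal	KLK3	literature
fine	luminal	KLK4	literature
fine	luminal	NKX3-1	literature
fine	luminal	STEAP2	literature
fine	basal	MMP7	literature
fine	basal	TEAD1	literature
fine	basal	KRT13	literature
fine	basal	KRT15	literature
fine	basal	KRT17	literature
fine	basal	KRT19	literature
fine	club	SCGB3A1	literature
fine	hillock	KRT13	literature
fine	endothelial	IGFBP7	literature
fine	endothelial	CD200	literature
fine	endothelial	CLDN5	literature
fine	endothelial	SELE	literature
fine	endothelial	VWF	literature
fine	endothelial	ENG	literature
fine	endothelial	IFI27	literature
fine	endothelial	EMCN	literature
fine	endothelial	CDH5	literature
fine	smooth_muscle	RGS5	literature
fine	smooth_muscle	MYH11	literature
fine	smooth_muscle	ACTG2	literature
fine	pericyte	RGS5	literature
fine	pericyte	NRP1	literature
fine	fibroblast	APOD	literature
fine	fibroblast	FBLN1	literature
fine	fibroblast	FGF2	literature
fine	fibroblast	PDGFRA	literature
fine	fibroblast	FBLN2	literature
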