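set_name	gene
NE	CHGA
NE	CHGB
NE	TPH1
NE	SYP
NE	ENO2
NE	NCAM1
NE	PCSK1N
NE	SCG2
NE	SCG3
NE	SCG5
NE	TTR
NE	GCH1
T	CD3D
T	CD3E
T	CD3G
T	CD2
T	TRAC
T	CD8A
T	IL7R
T	CCL5
T	LCK
T	CD7
B_plasma	CD79A
B_plasma	CD79B
B_plasma	MS4A1
B_plasma	IGHM
B_plasma	IGKC
B_plasma	IGLC1
B_plasma	JCHAIN
B_plasma	MZB1
B_plasma	DERL3
B_plasma	CD19
Macrophage	CD14
Macrophage	CD68
Macrophage	CD163
Macrophage	LYZ
Macrophage	AIF1
Macrophage	CSF1R
Macrophage	C1QA
Macrophage	C1QB
Macrophage	C1QC
Macrophage	MRC1
Fibroblast	COL1A1
Fibroblast	COL1A2
Fibroblast	COL3A1
Fibroblast	DCN
Fibroblast	LUM
Fibroblast	PDGFRA
Fibroblast	PDGFRB
Fibroblast	ACTA2
Fibroblast	TAGLN
Fibroblast	FAP
Endothelial	PECAM1
Endothelial	VWF
Endothelial	CDH5
Endothelial	CLDN5
Endothelial	FLT1
Endothelial	KDR
Endothelial	PLVAP
Endothelial	RAMP2
Endothelial	EGFL7
Endothelial	ENG
Epithelial	EPCAM
Epithelial	KRT8
Epithelial	KRT18
Epithelial	KRT19
Epithelial	CDH1
Epithelial	KRT7
Epithelial	LGALS4
Epithelial	FABP1
Epithelial	TFF3
Epithelial	VIL1
NK	NKG7
NK	GNLY
NK	KLRD1
NK	KLRF1
NK	NCR1
NK	PRF1
NK	GZMB
NK	KLRB1
NK	XCL1
NK	XCL2
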