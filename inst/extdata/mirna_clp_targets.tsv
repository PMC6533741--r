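# Published miRNA -> CL/P target-gene lists (16 enriched miRNAs), one pair per row
mirna	gene
hsa-miR-369-3p	CHD7
hsa-miR-369-3p	DMD
hsa-miR-369-3p	EYA1
hsa-miR-369-3p	GABRB3
hsa-miR-369-3p	GREM1
hsa-miR-369-3p	HOXB3
hsa-miR-369-3p	NOG
hsa-miR-369-3p	PAX6
hsa-miR-369-3p	TIMP2
hsa-miR-369-3p	TULP4
hsa-miR-369-3p	BAG4
hsa-miR-369-3p	FZD6
hsa-miR-369-3p	YOD1
hsa-miR-655-3p	BCL2
hsa-miR-655-3p	DMD
hsa-miR-655-3p	EN2
hsa-miR-655-3p	GREM1
hsa-miR-655-3p	HOXB3
hsa-miR-655-3p	MAFB
hsa-miR-655-3p	MID1
hsa-miR-655-3p	NTN1
hsa-miR-655-3p	PAX6
hsa-miR-655-3p	SATB2
hsa-miR-655-3p	TULP4
hsa-miR-655-3p	CYP1A1
hsa-miR-655-3p	FZD6
hsa-miR-655-3p	YOD1
hsa-miR-374a-5p	CHD7
hsa-miR-374a-5p	DMD
hsa-miR-374a-5p	EYA1
hsa-miR-374a-5p	FGFR2
hsa-miR-374a-5p	FOXG1
hsa-miR-374a-5p	HECTD1
hsa-miR-374a-5p	HOXB3
hsa-miR-374a-5p	JARID2
hsa-miR-374a-5p	MSX1
hsa-miR-374a-5p	NOG
hsa-miR-374a-5p	NTN1
hsa-miR-374a-5p	PAX6
hsa-miR-374a-5p	RAD51
hsa-miR-374a-5p	RHPN2
hsa-miR-374a-5p	RUNX2
hsa-miR-374a-5p	TGFA
hsa-miR-374a-5p	TNS1
hsa-miR-374a-5p	WNT5A
hsa-miR-374a-5p	WNT5B
hsa-miR-374a-5p	YOD1
hsa-miR-374a-5p	EN2
hsa-miR-374a-5p	FZD6
hsa-miR-374b-5p	CHD7
hsa-miR-374b-5p	DMD
hsa-miR-374b-5p	EYA1
hsa-miR-374b-5p	FGFR2
hsa-miR-374b-5p	FOXG1
hsa-miR-374b-5p	HECTD1
hsa-miR-374b-5p	HOXB3
hsa-miR-374b-5p	JARID2
hsa-miR-374b-5p	MSX1
hsa-miR-374b-5p	NOG
hsa-miR-374b-5p	NTN1
hsa-miR-374b-5p	PAX6
hsa-miR-374b-5p	RAD51
hsa-miR-374b-5p	RHPN2
hsa-miR-374b-5p	RUNX2
hsa-miR-374b-5p	TGFA
hsa-miR-374b-5p	TNS1
hsa-miR-374b-5p	WNT5A
hsa-miR-374b-5p	WNT5B
hsa-miR-374b-5p	YOD1
hsa-miR-374b-5p	EN2
hsa-miR-374b-5p	FZD6
hsa-miR-497-5p	AXIN2
hsa-miR-497-5p	BAG4
hsa-miR-497-5p	BCL2
hsa-miR-497-5p	CHD7
hsa-miR-497-5p	CRISPLD2
hsa-miR-497-5p	EN2
hsa-miR-497-5p	EYA1
hsa-miR-497-5p	FGF1
hsa-miR-497-5p	FGF2
hsa-miR-497-5p	FGFR1
hsa-miR-497-5p	FGFR2
hsa-miR-497-5p	FOXP2
hsa-miR-497-5p	FZD6
hsa-miR-497-5p	HECTD1
hsa-miR-497-5p	JARID2
hsa-miR-497-5p	PAX7
hsa-miR-497-5p	RHPN2
hsa-miR-497-5p	SATB2
hsa-miR-497-5p	SLC6A4
hsa-miR-497-5p	WNT3A
hsa-miR-497-5p	YOD1
hsa-miR-497-5p	MTHFR
hsa-miR-497-5p	RUNX2
hsa-miR-497-5p	TFAP2A
hsa-miR-497-5p	TPM1
hsa-miR-124-3p	GABRB3
hsa-miR-124-3p	GCH1
hsa-miR-124-3p	JAG2
hsa-miR-124-3p	KIF2A
hsa-miR-124-3p	MTR
hsa-miR-124-3p	MYH9
hsa-miR-124-3p	ROR2
hsa-miR-124-3p	RYK
hsa-miR-124-3p	TANC2
hsa-miR-124-3p	ARHGAP29
hsa-miR-124-3p	COL4A4
hsa-miR-124-3p	DVL2
hsa-miR-124-3p	EFNB1
hsa-miR-124-3p	FGF1
hsa-miR-124-3p	FGFR1
hsa-miR-124-3p	FOXF2
hsa-miR-124-3p	GREM1
hsa-miR-124-3p	HOXB3
hsa-miR-124-3p	KIF7
hsa-miR-124-3p	PDGFC
hsa-miR-124-3p	PEMT
hsa-miR-124-3p	PKP1
hsa-miR-124-3p	RAD51
hsa-miR-124-3p	RUNX2
hsa-miR-124-3p	SOX9
hsa-miR-124-3p	TBX22
hsa-miR-124-3p	TP63
hsa-miR-124-3p	TPM1
hsa-miR-124-3p	WNT5B
hsa-miR-1271-3p	CBS
hsa-miR-1271-3p	DCAF7
hsa-miR-1271-3p	FZD6
hsa-miR-1271-3p	RAD51
hsa-miR-1271-3p	YOD1
hsa-miR-203a-3p	E2F1
hsa-miR-203a-3p	EN2
hsa-miR-203a-3p	GREM1
hsa-miR-203a-3p	HECTD1
hsa-miR-203a-3p	KIF2A
hsa-miR-203a-3p	PAX6
hsa-miR-203a-3p	RUNX2
hsa-miR-203a-3p	SMAD2
hsa-miR-203a-3p	TP63
hsa-miR-27b-3p	BCL3
hsa-miR-27b-3p	CHD7
hsa-miR-27b-3p	COL21A1
hsa-miR-27b-3p	DVL2
hsa-miR-27b-3p	EN2
hsa-miR-27b-3p	EYA1
hsa-miR-27b-3p	FGF1
hsa-miR-27b-3p	FOXP2
hsa-miR-27b-3p	GABRB3
hsa-miR-27b-3p	GCH1
hsa-miR-27b-3p	GREM1
hsa-miR-27b-3p	HOXB3
hsa-miR-27b-3p	PAX9
hsa-miR-27b-3p	RARA
hsa-miR-27b-3p	SATB2
hsa-miR-27b-3p	SMAD1
hsa-miR-27b-3p	STK32B
hsa-miR-27b-3p	SMAD2
hsa-miR-27b-3p	DCAF7
hsa-miR-27b-3p	PAX3
hsa-miR-27b-3p	PAX7
hsa-miR-27b-3p	SEC16A
hsa-miR-27b-3p	WNT9B
hsa-miR-300	CR1
hsa-miR-300	DVL2
hsa-miR-300	FGF1
hsa-miR-300	FGFR2
hsa-miR-300	FOXF2
hsa-miR-300	FOXP2
hsa-miR-300	GABRB3
hsa-miR-300	GAD1
hsa-miR-300	HECTD1
hsa-miR-300	JAG2
hsa-miR-300	MID1
hsa-miR-300	PDGFC
hsa-miR-300	TANC2
hsa-miR-300	TGFB3
hsa-miR-300	WNT5A
hsa-miR-300	CRISPLD2
hsa-miR-300	GREM1
hsa-miR-300	PHF8
hsa-miR-3678-3p	E2F1
hsa-miR-3678-3p	GABRB3
hsa-miR-3678-3p	JARID2
hsa-miR-3678-3p	SLC6A4
hsa-miR-3678-3p	YOD1
hsa-miR-376b-3p	CRISPLD2
hsa-miR-376b-3p	EN2
hsa-miR-376b-3p	FGFR1
hsa-miR-376b-3p	MYH9
hsa-miR-376b-3p	PAX3
hsa-miR-376b-3p	PAX6
hsa-miR-376b-3p	PRSS35
hsa-miR-376b-3p	TANC2
hsa-miR-376b-3p	FGF2
hsa-miR-376b-3p	FOXG1
hsa-miR-381-3p	CR1
hsa-miR-381-3p	DVL2
hsa-miR-381-3p	FGF1
hsa-miR-381-3p	FGFR2
hsa-miR-381-3p	FOXF2
hsa-miR-381-3p	FOXP2
hsa-miR-381-3p	GABRB3
hsa-miR-381-3p	GAD1
hsa-miR-381-3p	HECTD1
hsa-miR-381-3p	JAG2
hsa-miR-381-3p	MID1
hsa-miR-381-3p	PDGFC
hsa-miR-381-3p	TANC2
hsa-miR-381-3p	TGFB3
hsa-miR-381-3p	WNT5A
hsa-miR-381-3p	CRISPLD2
hsa-miR-381-3p	GREM1
hsa-miR-381-3p	PHF8
hsa-miR-503-5p	HECTD1
hsa-miR-503-5p	JARID2
hsa-miR-503-5p	MAFB
hsa-miR-503-5p	WNT3A
hsa-miR-503-5p	BCL2
hsa-miR-503-5p	DHFR
hsa-miR-503-5p	FGF2
hsa-miR-503-5p	FGFR1
hsa-miR-503-5p	SMAD2
hsa-miR-503-5p	TFAP2A
hsa-miR-550a-3-5p	CBS
hsa-miR-550a-3-5p	DCAF7
hsa-miR-550a-3-5p	FZD6
hsa-miR-550a-3-5p	RAD51
hsa-miR-550a-3-5p	YOD1
hsa-miR-550a-5p	CBS
hsa-miR-550a-5p	DCAF7
hsa-miR-550a-5p	FZD6
hsa-miR-550a-5p	RAD51
hsa-miR-550a-5p	YOD1
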