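ligand	receptor	pair_id
VEGFA	FLT1	VEGFA_FLT1
VEGFA	KDR	VEGFA_KDR
VEGFA	NRP1	VEGFA_NRP1
BDNF	NTRK2	BDNF_NTRK2
TGFB1	TGFBR1	TGFB1_TGFBR1
APOE	LRP8	APOE_LRP8
PTN	PTPRZ1	PTN_PTPRZ1
NRG1	ERBB4	NRG1_ERBB4
FGF9	FGFR3	FGF9_FGFR3
TRH	TRHR	TRH_TRHR
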