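complex_id	members	bait	source_db	pub_id
TIM22_complex	TIM10|TIM12|TIM22|TIM54|TIM9		MIPS	
TIM9_TIM10	TIM10|TIM9		MIPS	
TFIIH_core	RAD3|SSL1|SSL2|TFB1|TFB2|TFB4		MIPS	
CAK	CCL1|KIN28|TFB3		MIPS	
SAGA	ADA2|ADA3|CHD1|GCN5|HFI1|SGF11|SGF29|SGF73|SPT20|SPT3|SPT7|SPT8|SUS1|TAF10|TAF12|TAF5|TAF6|TAF9|TRA1|UBP8		MIPS	
SALSA	ADA2|ADA3|GCN5|HFI1|SPT20|SPT3|SPT7|TAF12|TAF5|TAF6|TRA1		MIPS	
SLIK	ADA2|ADA3|CHD1|GCN5|HFI1|RTG2|SGF29|SPT20|SPT3|SPT7|TAF10|TAF12|TAF5|TAF6|TAF9|TRA1|UBP8		MIPS	
ADA_GCN5	ADA2|ADA3|GCN5|HFI1|SPT20		MIPS	
ORC	ORC1|ORC2|ORC3|ORC4|ORC5|ORC6		MIPS	
MCM	MCM2|MCM3|MCM4|MCM5|MCM6|MCM7		MIPS	
MAPs	ASE1|ATG4|ATG8|BIK1|BIM1|CBF5|CIN2|CIN4|MHP1|RBL2|SPC98|STU1|STU2|YTM1		MIPS	
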