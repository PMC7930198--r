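AR	synthetic placeholder: illustrative androgen-receptor activity markers, not the published signature	AR	KLK2	KLK3	TMPRSS2	NKX3-1	FOLH1	STEAP1	STEAP2	HOXB13	PMEPA1	PLPP1	ABCC4
NE	synthetic placeholder: illustrative neuroendocrine differentiation markers, not the published signature	SYP	CHGA	CHGB	ASCL1	NCAM1	ONECUT2	INSM1	SCG3	SYT4	ENO2	DLL3
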