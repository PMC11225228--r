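HALLMARK_TCA	tricarboxylic acid cycle enzymes	CS	ACO	IDH	OGDH	SUCLA	SDH	FH	MDH
HALLMARK_GLYCOLYSIS	lower glycolysis and pyruvate entry	PK	PDH	HK_OFF_NETWORK
HALLMARK_FA_TRANSPORT	carnitine shuttle	CRAT
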