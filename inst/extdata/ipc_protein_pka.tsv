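# pKa values of the nine ionizable groups, IPC_protein set (Kozlowski 2016,
# Biology Direct 11:55, Table: IPC_protein). Groups tagged acidic lose a
# proton (negative above pKa); basic groups gain one (positive below pKa).
group	pka	kind
N_terminal	9.094	basic
C_terminal	2.869	acidic
D	3.872	acidic
E	4.412	acidic
C	7.555	acidic
Y	10.85	acidic
H	5.637	basic
K	9.052	basic
R	11.84	basic
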