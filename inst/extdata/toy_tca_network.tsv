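source	target	reaction_id	reverse	source_type	target_type
pep	PK	R_PK	FALSE	metabolite	enzyme
PK	pyr	R_PK	FALSE	enzyme	metabolite
pyr	PDH	R_PDH	FALSE	metabolite	enzyme
PDH	accoa	R_PDH	FALSE	enzyme	metabolite
accoa	CS	R_CS	FALSE	metabolite	enzyme
oaa	CS	R_CS	FALSE	metabolite	enzyme
CS	cit	R_CS	FALSE	enzyme	metabolite
cit	ACO	R_ACO	FALSE	metabolite	enzyme
ACO	icit	R_ACO	FALSE	enzyme	metabolite
icit	IDH	R_IDH	FALSE	metabolite	enzyme
IDH	akg	R_IDH	FALSE	enzyme	metabolite
akg	OGDH	R_OGDH	FALSE	metabolite	enzyme
OGDH	succoa	R_OGDH	FALSE	enzyme	metabolite
succoa	SUCLA	R_SUCLA	FALSE	metabolite	enzyme
SUCLA	succ	R_SUCLA	FALSE	enzyme	metabolite
succ	SDH	R_SDH	FALSE	metabolite	enzyme
SDH	fum	R_SDH	FALSE	enzyme	metabolite
fum	FH	R_FH	FALSE	metabolite	enzyme
FH	mal	R_FH	FALSE	enzyme	metabolite
mal	MDH	R_MDH	TRUE	metabolite	enzyme
MDH	oaa	R_MDH	TRUE	enzyme	metabolite
accoa	CRAT	R_CRAT	FALSE	metabolite	enzyme
carn	CRAT	R_CRAT	FALSE	metabolite	enzyme
CRAT	acarn	R_CRAT	FALSE	enzyme	metabolite
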