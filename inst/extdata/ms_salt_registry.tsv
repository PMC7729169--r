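salt	group	molar_mass	ions
KNO3	macro	101.10	K:1;NO3:1
NH4NO3	macro	80.04	NH4:1;NO3:1
CaCl2.2H2O	macro	147.01	Ca:1;Cl:2
MgSO4.7H2O	macro	246.47	Mg:1;SO4:1
KH2PO4	macro	136.09	K:1;H2PO4:1
MnSO4.4H2O	micro	223.06	Mn:1;SO4:1
ZnSO4.7H2O	micro	287.56	Zn:1;SO4:1
H3BO3	micro	61.83	BO3:1
KI	micro	166.00	K:1;I:1
Na2MoO4.2H2O	micro	241.95	Na:2;MoO4:1
CuSO4.5H2O	micro	249.69	Cu:1;SO4:1
CoCl2.6H2O	micro	237.93	Co:1;Cl:2
Na2EDTA	iron	336.21	Na:2;EDTA:1
FeSO4.7H2O	iron	278.01	Fe:1;SO4:1
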