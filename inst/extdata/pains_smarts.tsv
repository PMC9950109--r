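rule_id	family	smarts	description
quinone_A	A	O=C1[#6]~[#6]C(=O)[#6]~[#6]1	para/ortho-quinone core
catechol_A	A	[OX2H][cX3]1[cX3]([OX2H])[cX3][cX3][cX3][cX3]1	catechol (1,2-dihydroxybenzene)
hzone_phenol_A	A	[OX2H]c1ccccc1/C=N/[!O]	phenolic hydrazone/imine
azo_A	A	[#6]N=N[#6]	azo linkage
rhod_sat_A	A	O=C1CSC(=S)N1	rhodanine core
ene_rhod_A	A	O=C1C(=[#6])SC(=S)N1	ene-rhodanine (alkylidene)
thiaz_ene_A	A	O=C1C(=[#6])SC(=N)N1	2-imino-thiazolidinone alkylidene
imine_one_A	A	O=C([#6])C([#6])=N[#7!$([#7][#6]=O)]	alpha-keto imine
mannich_A	A	[OX2H]c1ccccc1CN([#6])[#6]	phenolic Mannich base
anil_di_alk_A	A	c1cc([NX3]([CX4])[CX4])ccc1[CH]=[#6]	dialkylaminophenyl vinyl
ene_five_het_A	A	O=C1C(=[#6])N([#6,#1])C(=O)N1	alkylidene hydantoin/barbiturate
keto_keto_beta_A	A	O=C([#6])[CH2]C(=O)c1ccccc1	aryl beta-diketone
styrene_anil_A	A	c1ccccc1C=CC(=O)c1ccc(N)cc1	aminochalcone
cyano_ene_A	A	N#CC(=[#6])C(=O)[#6,#7,#8]	cyanoacrylate/acrylamide
quinone_methide_B	B	[#6]=C1C=CC(=O)C=C1	quinone methide
naphthoquinone_B	B	O=C1C(=O)c2ccccc2C=C1	1,2-naphthoquinone
anthranil_acyl_B	B	O=C([#6])c1ccccc1N	acyl anthranilamide motif
isothiaz_one_B	B	S1N=CC(=O)[#6]1	isothiazolinone
hydroquinone_C	C	[OX2H]c1ccc([OX2H])cc1	hydroquinone (1,4-dihydroxybenzene)
nitroso_C	C	[#6][NX2]=O	C-nitroso
diazonium_C	C	[#6][N+]#N	diazonium
thiourea_enamine_C	C	NC(=S)N/C=C/[#6]	thiourea enamine
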