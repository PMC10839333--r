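molecule	lipid_class	peak_id	conc_mM	protons	area	temperature	NS	P1	RG
triolein	TG	tg_glycerol_43	36.7	4	403.552214765101	298	128	10	64
tripalmitin	TG	tg_glycerol_43	36.7	4	403.552214765101	298	128	10	64
trilinolein	TG	tg_glycerol_43	36.7	4	403.552214765101	298	128	10	64
dipalmitoyl-PC	PC_LPC	choline	10	9	247.409395973154	298	128	10	64
dioleoyl-PC	PC_LPC	choline	10	9	247.409395973154	298	128	10	64
palmitoyl-LPC	PC_LPC	choline	10	9	247.409395973154	298	128	10	64
dipalmitoyl-PE	PE	pe_ch2	10	2	54.9798657718121	298	128	10	64
dioleoyl-PE	PE	pe_ch2	10	2	54.9798657718121	298	128	10	64
cholesterol	TC	tc_ch3	10	3	82.4697986577181	298	128	10	64
cholesteryl-oleate	CE	tc_ch3	10	3	82.4697986577181	298	128	10	64
cholesteryl-palmitate	CE	tc_ch3	10	3	82.4697986577181	298	128	10	64
palmitic-acid	FA	fa_ch3	10	3	82.4697986577181	298	128	10	64
stearic-acid	FA	fa_ch3	10	3	82.4697986577181	298	128	10	64
oleic-acid	FA	fa_ch3	10	3	82.4697986577181	298	128	10	64
linoleic-acid	FA	fa_ch3	10	3	82.4697986577181	298	128	10	64
alpha-linolenic-acid	omega3	omega3_ch3	10	3	82.4697986577181	298	128	10	64
diolein	DG	tg_glycerol_43	10	2	54.9798657718121	298	128	10	64
monoolein	MG	tg_glycerol_43	10	2	54.9798657718121	298	128	10	64
sphingomyelin	SM	choline	10	9	247.409395973154	298	128	10	64
phosphatidylinositol	PI	pe_ch2	10	2	54.9798657718121	298	128	10	64
palmitoleic-acid	FA	fa_ch3	10	3	82.4697986577181	298	128	10	64
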