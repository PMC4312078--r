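family_id	biosynthetic_class	product	duplicate_in	multi_contig_in	J1074	PVA-94-07	GBA-94-10	SM8	LaPpAH-202	S4
c01	Hopene / Squalene synthase	Hopanoids		SM8	1	1	1	1	1	1
c02	NRPS-independent siderophore synthase	Desferrioxamine			1	1	1	1	1	1
c03	NRPS-independent siderophore synthase	Aerobactin-like		SM8	1	1	1	1	1	1
c04	Ectoine synthase	Ectoine			1	1	1	1	1	1
c05	Phytoene / polyprenyl synthetase	Carotenoids			1	1	1	1	1	1
c06	Terpene synthase	Geosmin			1	1	1	1	1	1
c07	Terpene	Albaflavenone			1	1	1	1	1	1
c08	Type III PKS	Tetrahydroxynapthalene			1	1	1	1	1	1
c09	Type I PKS	Candicidin		SM8;LaPpAH-202;S4	1	1	1	1	1	1
c10	Type I PKS	Unknown		SM8;S4	1	1	1	1	1	1
c11	Hybrid NRPS / PKS	Antimycin		LaPpAH-202	1	1	1	1	1	1
c12	Hybrid NRPS / PKS	Alteramide			1	1	1	1	1	1
c13	Hybrid NRPS / PKS	Unknown		SM8	1	1	1	1	1	1
c14	NRPS	Gramicidin-like		SM8;LaPpAH-202	1	1	1	1	1	1
c15	NRPS	Unknown			1	1	1	1	1	1
c16	Bacteriocin	Unknown			1	1	1	1	1	1
c17	Bacteriocin	Unknown			1	1	1	1	1	1
c18	Lantipeptide	SapB			1	1	1	1	1	1
a01	Hybrid NRPS / PKS	Unknown		S4	1	1	0	1	1	1
a02	NRPS	Unknown		LaPpAH-202	1	0	0	0	1	0
a03	Lantipeptide	Unknown			1	1	1	0	1	1
a04	NRPS	Unknown		SM8;S4	1	0	0	1	1	1
a05	NRPS	Indigoidin			1	0	0	0	1	0
a06	Terpene	Unknown			0	1	1	1	1	1
a07	Hybrid NRPS / PKS	Kijanimycin-like			0	1	1	0	0	0
a08	Type I PKS	Unknown			0	1	1	0	0	0
a09	NRPS	Unknown			0	1	1	0	0	0
a10	NRPS	Unknown			0	1	1	0	0	0
a11	NRPS	Unknown			0	1	1	0	0	0
a12	NRPS	Unknown	PVA-94-07;GBA-94-10		0	1	1	0	0	0
a13	Type I PKS-butyrolactone	Unknown	PVA-94-07;GBA-94-10		0	1	1	0	0	0
a14	Type II PKS	Enterocin			0	1	1	0	0	0
s01	NRPS / Oligosaccharide	Paulomycin			1	0	0	0	0	0
s02	Bacteriocin	Unknown			1	0	0	0	0	0
s03	Lantipeptide	Unknown			0	1	0	0	0	0
s04	Other	Unknown			0	0	1	0	0	0
s05	Type II PKS	Unknown			0	0	0	1	0	0
s06	Butyrolactone	Unknown			0	0	0	1	0	0
s07	Bacteriocin	Unknown			0	0	0	1	0	0
s08	NRPS	Unknown			0	0	0	0	1	0
s09	NRPS	Unknown			0	0	0	0	1	0
s10	Type I PKS	Unknown		LaPpAH-202	0	0	0	0	1	0
s11	Other	Unknown			0	0	0	0	0	1
s12	Type I PKS / Type III PKS	Kendomycin			0	0	0	0	0	1
s13	NRPS	Mannopeptimycin-like			0	0	0	0	0	1
s14	Butyrolactone	Unknown			0	0	0	0	0	1
s15	Bacteriocin	Unknown			0	0	0	0	0	1
s16	Type II PKS	Fredericamycin			0	0	0	0	0	1
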