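NANOG	act	OCT4	text
OCT4SOX2	act	OCT4	text
NANOG	act	SOX2	text
OCT4SOX2	act	SOX2	text
NANOG	act	NANOG	text
OCT4SOX2	act	NANOG	text
KLF4	act	NANOG	text
ZIC3	act	NANOG	text
PBX1	act	NANOG	text
OCT4	act	OCT4SOX2	text
SOX2	act	OCT4SOX2	text
SOX2	act	ZIC3	text
NANOG	act	ZIC3	text
NANOG	act	PBX1	text
GATA6	act	GATA6	text
CDX2	act	CDX2	text
GATA6	act	SOX17	figure
SOX17	act	GATA6	figure
GATA6	act	FOXA2	figure
FOXA2	act	GATA6	figure
CDX2	act	GATA2	figure
GATA2	act	CDX2	figure
CDX2	act	GATA3	figure
GATA3	act	CDX2	figure
GATA6	act	AFP	figure
GATA6	act	GATA4	figure
CDX2	act	T	figure
GATA3	act	HCGA	figure
GATA3	act	HCGB	figure
NANOG	act	LIN28	figure
OCT4	act	LIN28	figure
NANOG	act	SALL4	figure
OCT4	act	SALL4	figure
NANOG	act	DPPA4	figure
OCT4	act	DPPA4	figure
NANOG	act	DPPA2	figure
OCT4	act	DPPA2	figure
NANOG	act	TERT	figure
OCT4	act	TERT	figure
NANOG	act	DNMT3B	figure
OCT4	act	DNMT3B	figure
NANOG	act	LEFTY1	figure
OCT4	act	LEFTY1	figure
NANOG	act	LEFTY2	figure
OCT4	act	LEFTY2	figure
NANOG	act	NODAL	figure
OCT4	act	NODAL	figure
NANOG	act	FGF4	figure
OCT4	act	FGF4	figure
NANOG	act	STAT3	figure
OCT4	act	STAT3	figure
NANOG	act	ESRRB	figure
OCT4	act	ESRRB	figure
NANOG	act	TBX3	figure
OCT4	act	TBX3	figure
NANOG	act	REST	figure
OCT4	act	REST	figure
NANOG	act	MYC	figure
OCT4	act	MYC	figure
NANOG	act	PRDM14	figure
OCT4	act	PRDM14	figure
NANOG	act	LMCD1	figure
OCT4	act	LMCD1	figure
GATA6	act	OTX2	figure
CDX2	act	GBX2	figure
GATA6	act	HESX1	figure
CDX2	act	SOX15	figure
GATA6	act	FOXO1	figure
CDX2	act	SMAD2	figure
GATA4	act	TCF3	figure
GATA6	act	PITX2	figure
CDX2	act	HAND1	figure
GATA6	act	EOMES	figure
CDX2	act	MSX2	figure
GATA6	act	KRT18	figure
CDX2	act	SPARC	figure
GATA4	act	OTX2	figure
GATA4	act	GBX2	figure
SOX17	act	HESX1	figure
SOX17	act	SOX15	figure
GATA3	act	FOXO1	figure
GATA2	act	SMAD2	figure
GATA4	act	KRT18	figure
SOX17	act	SPARC	figure
CDX2	rep	OCT4	text
OCT4	rep	CDX2	text
NANOG	rep	GATA6	text
GATA6	rep	NANOG	text
OCT4	rep	GATA6	text
GATA4	rep	GATA6	text
LMCD1	rep	GATA6	text
PRDM14	rep	GATA6	text
NANOG	rep	CDX2	figure
SOX2	rep	CDX2	figure
OCT4	rep	FOXA2	figure
SOX2	rep	FOXA2	figure
NANOG	rep	GATA4	figure
OCT4	rep	SOX17	figure
SOX2	rep	SOX17	figure
NANOG	rep	T	figure
OCT4	rep	GATA2	figure
NANOG	rep	GATA3	figure
OCT4	rep	HCGA	figure
NANOG	rep	HCGB	figure
OCT4	rep	AFP	figure
CDX2	rep	NANOG	figure
GATA6	rep	SOX2	figure
GATA6	rep	KLF4	figure
CDX2	rep	KLF4	figure
GATA6	rep	FOXD3	figure
CDX2	rep	FOXD3	figure
GATA6	rep	ZFP42	figure
CDX2	rep	GDF3	figure
GATA6	rep	TDGF1	figure
CDX2	rep	ZIC3	figure
GATA6	rep	PBX1	figure
GATA6	rep	OCT4SOX2	figure
TBX3	rep	CDX2	figure
ESRRB	rep	CDX2	figure
OTX2	rep	NANOG	figure
EOMES	rep	OCT4	figure
HAND1	rep	SOX2	figure
REST	rep	T	figure
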