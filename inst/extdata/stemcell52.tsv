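NANOG	act	OCT4
OCT4SOX2	act	OCT4
NANOG	act	SOX2
OCT4SOX2	act	SOX2
NANOG	act	NANOG
OCT4SOX2	act	NANOG
KLF4	act	NANOG
ZIC3	act	NANOG
PBX1	act	NANOG
OCT4	act	OCT4SOX2
SOX2	act	OCT4SOX2
SOX2	act	ZIC3
NANOG	act	ZIC3
NANOG	act	PBX1
GATA6	act	GATA6
CDX2	act	CDX2
GATA6	act	SOX17
SOX17	act	GATA6
GATA6	act	FOXA2
FOXA2	act	GATA6
CDX2	act	GATA2
GATA2	act	CDX2
CDX2	act	GATA3
GATA3	act	CDX2
GATA6	act	AFP
GATA6	act	GATA4
CDX2	act	T
GATA3	act	HCGA
GATA3	act	HCGB
NANOG	act	LIN28
OCT4	act	LIN28
NANOG	act	SALL4
OCT4	act	SALL4
NANOG	act	DPPA4
OCT4	act	DPPA4
NANOG	act	DPPA2
OCT4	act	DPPA2
NANOG	act	TERT
OCT4	act	TERT
NANOG	act	DNMT3B
OCT4	act	DNMT3B
NANOG	act	LEFTY1
OCT4	act	LEFTY1
NANOG	act	LEFTY2
OCT4	act	LEFTY2
NANOG	act	NODAL
OCT4	act	NODAL
NANOG	act	FGF4
OCT4	act	FGF4
NANOG	act	STAT3
OCT4	act	STAT3
NANOG	act	ESRRB
OCT4	act	ESRRB
NANOG	act	TBX3
OCT4	act	TBX3
NANOG	act	REST
OCT4	act	REST
NANOG	act	MYC
OCT4	act	MYC
NANOG	act	PRDM14
OCT4	act	PRDM14
NANOG	act	LMCD1
OCT4	act	LMCD1
GATA6	act	OTX2
CDX2	act	GBX2
GATA6	act	HESX1
CDX2	act	SOX15
GATA6	act	FOXO1
CDX2	act	SMAD2
GATA4	act	TCF3
GATA6	act	PITX2
CDX2	act	HAND1
GATA6	act	EOMES
CDX2	act	MSX2
GATA6	act	KRT18
CDX2	act	SPARC
GATA4	act	OTX2
GATA4	act	GBX2
SOX17	act	HESX1
SOX17	act	SOX15
GATA3	act	FOXO1
GATA2	act	SMAD2
GATA4	act	KRT18
SOX17	act	SPARC
CDX2	rep	OCT4
OCT4	rep	CDX2
NANOG	rep	GATA6
GATA6	rep	NANOG
OCT4	rep	GATA6
GATA4	rep	GATA6
LMCD1	rep	GATA6
PRDM14	rep	GATA6
NANOG	rep	CDX2
SOX2	rep	CDX2
OCT4	rep	FOXA2
SOX2	rep	FOXA2
NANOG	rep	GATA4
OCT4	rep	SOX17
SOX2	rep	SOX17
NANOG	rep	T
OCT4	rep	GATA2
NANOG	rep	GATA3
OCT4	rep	HCGA
NANOG	rep	HCGB
OCT4	rep	AFP
CDX2	rep	NANOG
GATA6	rep	SOX2
GATA6	rep	KLF4
CDX2	rep	KLF4
GATA6	rep	FOXD3
CDX2	rep	FOXD3
GATA6	rep	ZFP42
CDX2	rep	GDF3
GATA6	rep	TDGF1
CDX2	rep	ZIC3
GATA6	rep	PBX1
GATA6	rep	OCT4SOX2
TBX3	rep	CDX2
ESRRB	rep	CDX2
OTX2	rep	NANOG
EOMES	rep	OCT4
HAND1	rep	SOX2
REST	rep	T
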