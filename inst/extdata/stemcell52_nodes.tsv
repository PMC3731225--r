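OCT4	1	stem_marker
SOX2	2	stem_marker
NANOG	3	stem_marker
OCT4SOX2	4	stem_marker
KLF4	5	stem_marker
FOXD3	6	stem_marker
ZIC3	7	stem_marker
ZFP42	8	stem_marker
GDF3	9	stem_marker
TDGF1	10	stem_marker
PBX1	11	stem_marker
FOXA2	12	diff_marker
AFP	13	diff_marker
SOX17	14	diff_marker
GATA4	15	diff_marker
GATA6	16	diff_marker
T	17	diff_marker
GATA2	18	diff_marker
GATA3	19	diff_marker
HCGA	20	diff_marker
HCGB	21	diff_marker
CDX2	22	diff_marker
LIN28	23	stem_activated
SALL4	24	stem_activated
DPPA4	25	stem_activated
DPPA2	26	stem_activated
TERT	27	stem_activated
DNMT3B	28	stem_activated
LEFTY1	29	stem_activated
LEFTY2	30	stem_activated
NODAL	31	stem_activated
FGF4	32	stem_activated
STAT3	33	stem_activated
ESRRB	34	stem_activated
TBX3	35	stem_activated
REST	36	stem_activated
MYC	37	stem_activated
PRDM14	38	stem_activated
LMCD1	39	stem_activated
OTX2	40	other
GBX2	41	other
HESX1	42	other
SOX15	43	other
FOXO1	44	other
SMAD2	45	other
TCF3	46	other
PITX2	47	other
HAND1	48	other
EOMES	49	other
MSX2	50	other
KRT18	51	other
SPARC	52	other
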