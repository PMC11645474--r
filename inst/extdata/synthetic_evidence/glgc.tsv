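gene	tc_p	tg_p	ldl_p	hdl_p
QTRT1	3.65e-16	NA	2.18e-19	NA
PPARD	1.61e-07	NA	5.65e-06	NA
CABP1	NA	NA	2.87e-05	NA
LDLR	5.43e-202	NA	3.85e-262	6.32e-05
HLA-E	5.15e-07	1.35e-09	NA	4.01e-05
GBA	NA	NA	NA	NA
ADGRA2	NA	NA	NA	NA
SPRYD3	NA	NA	NA	NA
RASGEF1B	NA	NA	NA	NA
TOE1	NA	NA	NA	NA
APBB2	NA	NA	NA	NA
LTF	NA	NA	NA	NA
TP53BP1	NA	NA	NA	NA
FGB	NA	NA	NA	NA
HPSE2	NA	NA	NA	NA
MNS1	NA	NA	NA	NA
PM20D1	NA	NA	NA	NA
SLK	NA	NA	NA	NA
KLHL8	1.2e-06	NA	NA	NA
PCSK5	2.4e-06	NA	NA	NA
C2orf73	NA	NA	NA	3.1e-06
SYNA1	4.5e-08	NA	6.7e-07	NA
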