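gene	category
QTRT1	cardiovascular
QTRT1	metabolism
LDLR	cardiovascular
LDLR	metabolism
CABP1	cardiovascular
PPARD	metabolism
HLA-E	metabolism
TOE1	metabolism
HPSE2	liver
CHST14	cardiovascular
KLHL8	metabolism
FBLN5	cardiovascular
PCSK5	cardiovascular
TOP2A	cardiovascular
RALY	metabolism
SYNC1	adipose
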