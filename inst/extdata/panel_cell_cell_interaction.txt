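# Cell-cell interaction molecule panel (editable default; one HGNC symbol per line)
HLA-A
HLA-B
HLA-C
HLA-DRA
HLA-DRB1
HLA-DPA1
HLA-DPB1
HLA-DQA1
HLA-DQB1
B2M
ICAM1
VCAM1
ITGAL
ITGB2
CD2
CD58
CD80
CD86
CD28
CD40
CD40LG
ICOS
ICOSLG
PDCD1LG2
LGALS9
HAVCR2
LAG3
TIGIT
PVR
NECTIN2
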