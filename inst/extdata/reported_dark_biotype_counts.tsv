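biotype	array_dark	most_dili	no_dili	dark_degs
protein_coding	1756	444	278	567
antisense	527	69	33	78
lincRNA	722	53	33	63
processed_transcript	113	11	8	15
pseudogene	56	18	14	25
snoRNA	8	4	3	5
sense_intronic	25	3	1	3
sense_overlapping	10	1	1	2
miRNA	3	1	0	1
TEC	11	1	1	1
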