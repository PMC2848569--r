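location	correct_v1	correct_v2	total
Acrosome	0	1	14
Cell membrane	262	452	697
Cell wall	4	6	49
Centrosome	9	22	96
Chloroplast	117	318	385
Cyanelle	12	47	79
Cytoplasm	918	1418	2186
Cytoskeleton	4	44	139
Endoplasmic reticulum	115	348	457
Endosome	1	2	41
Extracell	678	858	1048
Golgi apparatus	5	56	254
Hydrogenosome	0	2	10
Lysosome	5	26	57
Melanosome	0	0	47
Microsome	0	1	13
Mitochondrion	143	427	610
Nucleus	1212	1501	2320
Peroxisome	1	56	110
Spindle pole body	0	23	68
Synapse	0	0	47
Vacuole	7	101	170
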