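class	coral_reef	kelp_forest	mangrove_forest	seagrass_bed	total
Actinopterygii	1256	29	31	243	1559
Anthozoa	994	7	2	11	1014
Liliopsida	45	2	26	553	626
Malacostraca	233	29	90	236	588
Magnoliopsida	34	0	350	17	401
Phaeophyceae	145	122	3	28	298
Gastropoda	102	26	50	47	225
Echinoidea	115	34	2	39	190
Demospongiae	159	0	6	24	189
Bivalvia	86	2	18	79	185
Florideophyceae	124	9	4	33	170
Polychaeta	68	5	11	49	133
Hydrozoa	109	3	4	4	120
Bryopsidophyceae	57	2	0	41	100
Asteroidea	78	2	1	11	92
Ulvophyceae	46	2	3	31	82
Gymnolaemata	77	1	0	2	80
Maxillopoda	40	2	12	23	77
Mammalia	15	12	7	27	61
Ascidiacea	30	2	0	5	37
Insecta	0	0	32	1	33
Holothuroidea	20	0	0	13	33
Aves	4	2	15	10	31
Reptilia	22	0	2	7	31
Tentaculata	29	0	0	0	29
Elasmobranchii	22	0	1	5	28
Trematoda	27	0	1	0	28
Monogenea	20	0	1	1	22
Adenophorea	8	0	7	3	18
Scyphozoa	16	0	0	0	16
Ophiuroidea	15	0	0	1	16
Thaliacea	1	0	0	12	13
Bacillariophyceae	4	0	3	4	11
Ostracoda	5	0	2	4	11
Chlorophyceae	6	1	1	2	10
Crinoidea	6	0	4	0	10
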