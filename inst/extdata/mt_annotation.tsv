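name	start	end	strand	type
CR	16024	16569	heavy	control
CR	1	576	heavy	control
TF	577	647	heavy	tRNA
RNR1	648	1601	heavy	rRNA
TV	1602	1670	heavy	tRNA
RNR2	1671	3229	heavy	rRNA
TL1	3230	3304	heavy	tRNA
ND1	3307	4262	heavy	protein
TI	4263	4331	heavy	tRNA
TQ	4329	4400	light	tRNA
TM	4402	4469	heavy	tRNA
ND2	4470	5511	heavy	protein
TW	5512	5579	heavy	tRNA
TA	5587	5655	light	tRNA
TN	5657	5729	light	tRNA
TC	5761	5826	light	tRNA
TY	5826	5891	light	tRNA
CO1	5904	7445	heavy	protein
TS1	7446	7514	light	tRNA
TD	7518	7585	heavy	tRNA
CO2	7586	8269	heavy	protein
TK	8295	8364	heavy	tRNA
ATP8	8366	8572	heavy	protein
ATP6	8527	9207	heavy	protein
CO3	9207	9990	heavy	protein
TG	9991	10058	heavy	tRNA
ND3	10059	10404	heavy	protein
TR	10405	10469	heavy	tRNA
ND4L	10470	10766	heavy	protein
ND4	10760	12137	heavy	protein
TH	12138	12206	heavy	tRNA
TS2	12207	12265	heavy	tRNA
TL2	12266	12336	heavy	tRNA
ND5	12337	14148	heavy	protein
ND6	14149	14673	light	protein
TE	14674	14742	light	tRNA
CYB	14747	15887	heavy	protein
TT	15888	15953	heavy	tRNA
TP	15956	16023	light	tRNA
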