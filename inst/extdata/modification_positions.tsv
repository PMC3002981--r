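short_name	positions	note
D	16,17,20	D-loop dihydrouridines
Y	27,28,38,39,55	widespread; anticodon stem and T-loop
m5C	34,40,48,49	Trm4 product
Cm	32,34	anticodon loop; Trm7 product
m5U	54	T-loop; Trm2 product
ncm5U	34	wobble
ac4C	12	Tan1 product
m3C	32	anticodon loop
ncm5Um	34	wobble; Trm7 2'-O-methylation of ncm5U
Um	44	variable arm; Trm44 product (redundant 2'-O-methylation)
m7G	46	core; Trm8/Trm82 heterodimer product
m1A	58	T-loop
mcm5U	34	wobble; Trm9 product
m1I	37	Trm5 methylation of inosine 37
Gm	18,34	D-loop (Trm3) and wobble (Trm7)
m1G	9,37	Trm10 (9) and Trm5 (37)
m2G	10	Trm11 product
I	34	wobble inosine; Tad deaminase pathway
mcm5s2U	34	wobble; Trm9 product
m22G	26	Trm1 product
t6A	37	anticodon-adjacent
Am	4,18	acceptor stem (Trm13) and D-loop
yW	37	wybutosine pathway (Trm5, Trm12)
i6A	37	Mod5 product
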