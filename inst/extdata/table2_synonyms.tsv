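group	species_a	species_b	anib	earlier_synonym
P. aeruginosa group	P. citronellolis	P. humi	96.70	P. citronellolis
P. aeruginosa group	P. nitroreducens	P. nitritireducens	98.85	P. nitroreducens
P. oleovorans group	P. oleovorans	P. pseudoalcaligenes	97.17	P. oleovorans
P. oleovorans group	P. chengduensis	P. sihuiensis	96.25	P. chengduensis
P. oryzihabitans group	P. oryzihabitans	P. psychrotolerans	98.22	P. oryzihabitans
P. oryzihabitans group	P. luteola	P. zeshuii	97.87	P. luteola
P. pertucinogena group	P. phragmitis	P. jilinensis	98.70	P. phragmitis
P. pertucinogena group	P. gallaeciensis	P. abyssi	97.56	P. gallaeciensis
P. putida group	P. asiatica	P. pyomelaninifaciens	99.03	P. asiatica
P. putida group		P. shirazica	99.17	
P. stutzeri group	P. chloritidismutans	P. kunmingensis	96.49	P. chloritidismutans
P. syringae group	P. tremae	P. coronafaciens	98.74	P. tremae
P. syringae group	P. amygdali	P. ficuserectae	97.42	P. amygdali
P. syringae group		P. meliae	98.27	
P. syringae group		P. savastanoi	98.75	
P. fluorescens group	P. asplenii	P. fuscovaginae	98.23	P. asplenii
P. fluorescens group	P. veronii	P. panacis	99.95	P. veronii
Orphan groups	P. flexibilis	P. tuomuerensis	98.69	P. flexibilis
Orphan groups	P. fluvialis	P. pharmacofabricae	98.61	P. fluvialis
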