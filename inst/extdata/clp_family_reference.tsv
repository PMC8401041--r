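family	total_modules	per_gene_modules	notes
Viscosin/WLIP	9	2,4,3	nonapeptide; curated from published viscosin/WLIP NRPS annotations
Putisolvin	12	2,7,3	dodecapeptide; curated from published putisolvin NRPS annotations
Entolysin	14	2,5,7	tetradecapeptide; curated from published entolysin NRPS annotations
Xantholysin	14	2,8,4	tetradecapeptide; curated from published xantholysin NRPS annotations
LP-13	13	2,5,6	lipotridecapeptide; 13-module total published, per-gene distribution provisional
N8	17	2,7,8	17:8 CLP; provisional stub, distribution unpublished
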