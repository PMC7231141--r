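gene_id	chrom	start	end
ZNF707	8	144824516	144849514
NAPRT1	8	144728101	144731656
APBA3	19	3701771	3712673
C8orf58	8	22513067	22517605
KIAA1967	8	22518202	22533920
RHOBTB2	8	22913059	22933655
TNFRSF10B	8	22933598	22982637
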