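rsid	gene_id	p_reported
rs4873815	ZNF707	8.92e-4
rs4873815	NAPRT1	4.41e-4
rs12976454	APBA3	3.40e-4
rs11136002	C8orf58	5.53e-4
rs11136002	KIAA1967	9.19e-4
rs11136002	RHOBTB2	3.12e-4
rs11136002	TNFRSF10B	4.03e-4
rs13259097	RHOBTB2	3.87e-4
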