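rsid	chrom	pos	cytoband
rs4873815	8	144796206	8q24.3
rs12976454	19	3495971	19p13.3
rs11136002	8	22273027	8p21.3
rs13259097	8	22189689	8p21.3
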