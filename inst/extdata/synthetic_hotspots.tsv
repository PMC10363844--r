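type	hugo_symbol	protein_position	hgvsp_short	start_position	end_position
snv	TP53	175	NA	NA	NA
snv	TP53	245	NA	NA	NA
snv	TP53	248	NA	NA	NA
snv	TP53	273	NA	NA	NA
snv	TP53	282	NA	NA	NA
snv	BRAF	600	NA	NA	NA
snv	H3F3A	28	NA	NA	NA
snv	H3F3A	35	NA	NA	NA
snv	HIST1H3B	28	NA	NA	NA
snv	IDH1	132	NA	NA	NA
snv	FGFR1	546	NA	NA	NA
snv	FGFR1	577	NA	NA	NA
snv	FGFR1	656	NA	NA	NA
snv	FGFR1	687	NA	NA	NA
snv	KRAS	12	NA	NA	NA
snv	CTNNB1	33	NA	NA	NA
snv	PIK3CA	545	NA	NA	NA
splice	TP53	NA	p.X125_splice	NA	NA
splice	MET	NA	p.X1010_splice	NA	NA
indel	TP53	NA	NA	102	292
indel	EGFR	NA	NA	745	755
indel	CTNNB1	NA	NA	32	45
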