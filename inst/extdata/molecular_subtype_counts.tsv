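broad_histology	molecular_subtype	patients	tumors
Chordoma	CHDM, conventional	2	2
Chordoma	CHDM, poorly differentiated	2	4
Embryonal tumor	CNS embryonal, NOS	13	13
Embryonal tumor	CNS HGNET-MN1	1	1
Embryonal tumor	CNS NB-FOXR2	2	3
Embryonal tumor	ETMR, C19MC altered	5	5
Embryonal tumor	ETMR, NOS	1	1
Embryonal tumor	MB, group 3	14	14
Embryonal tumor	MB, group 4	48	49
Embryonal tumor	MB, SHH	24	30
Embryonal tumor	MB, WNT	10	10
Ependymoma	EPN, H3 K28	1	1
Ependymoma	EPN, ST RELA	25	28
Ependymoma	EPN, ST YAP1	3	4
High-grade glioma	DMG, H3 K28	18	24
High-grade glioma	DMG, H3 K28, TP53 activated	10	13
High-grade glioma	DMG, H3 K28, TP53 loss	30	40
High-grade glioma	HGG, H3 G35	3	3
High-grade glioma	HGG, H3 G35, TP53 loss	1	1
High-grade glioma	HGG, H3 wild type	26	31
High-grade glioma	HGG, H3 wild type, TP53 activated	5	5
High-grade glioma	HGG, H3 wild type, TP53 loss	14	21
High-grade glioma	HGG, IDH, TP53 activated	1	2
High-grade glioma	HGG, IDH, TP53 loss	1	1
Low-grade glioma	GNG, BRAF V600E	13	13
Low-grade glioma	GNG, BRAF V600E, CDKN2A/B	1	1
Low-grade glioma	GNG, FGFR	1	1
Low-grade glioma	GNG, H3	1	1
Low-grade glioma	GNG, IDH	1	2
Low-grade glioma	GNG, KIAA1549-BRAF	5	5
Low-grade glioma	GNG, MYB/MYBL1	1	1
Low-grade glioma	GNG, NF1-germline	1	1
Low-grade glioma	GNG, NF1-somatic, BRAF V600E	1	1
Low-grade glioma	GNG, other MAPK	4	4
Low-grade glioma	GNG, other MAPK, IDH	1	1
Low-grade glioma	GNG, RTK	2	3
Low-grade glioma	GNG, wild type	14	14
Low-grade glioma	LGG, BRAF V600E	25	27
Low-grade glioma	LGG, BRAF V600E, CDKN2A/B	5	5
Low-grade glioma	LGG, FGFR	8	8
Low-grade glioma	LGG, IDH	3	3
Low-grade glioma	LGG, KIAA1549-BRAF	106	113
Low-grade glioma	LGG, KIAA1549-BRAF, NF1-germline	1	1
Low-grade glioma	LGG, KIAA1549-BRAF, other MAPK	1	1
Low-grade glioma	LGG, MYB/MYBL1	2	2
Low-grade glioma	LGG, NF1-germline	6	6
Low-grade glioma	LGG, NF1-germline, CDKN2A/B	1	1
Low-grade glioma	LGG, NF1-germline, FGFR	1	2
Low-grade glioma	LGG, NF1-somatic	2	2
Low-grade glioma	LGG, NF1-somatic, FGFR	1	1
Low-grade glioma	LGG, NF1-somatic, NF1-germline, CDKN2A/B	1	1
Low-grade glioma	LGG, other MAPK	11	12
Low-grade glioma	LGG, RTK	8	10
Low-grade glioma	LGG, RTK, CDKN2A/B	1	1
Low-grade glioma	LGG, wild type	33	34
Low-grade glioma	SEGA, RTK	1	1
Low-grade glioma	SEGA, wild type	10	11
Mesenchymal non-meningothelial tumor	EWS	9	11
Neuronal and mixed neuronal-glial tumor	CNC	2	2
Neuronal and mixed neuronal-glial tumor	EVN	1	1
Neuronal and mixed neuronal-glial tumor	GNT, BRAF V600E	1	1
Neuronal and mixed neuronal-glial tumor	GNT, KIAA1549-BRAF	1	2
Neuronal and mixed neuronal-glial tumor	GNT, other MAPK	1	1
Neuronal and mixed neuronal-glial tumor	GNT, other MAPK, FGFR	1	1
Neuronal and mixed neuronal-glial tumor	GNT, RTK	1	2
Tumor of sellar region	CRANIO, ADAM	27	27
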