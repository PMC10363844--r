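name	category
BRAF	kinase
ALK	kinase
NTRK1	kinase
NTRK2	kinase
NTRK3	kinase
ROS1	kinase
FGFR1	kinase
FGFR2	kinase
MET	kinase
KIT	kinase
PDGFRA	kinase
RAF1	kinase
EGFR	kinase
MYB	oncogene
MYBL1	oncogene
SNCAIP	oncogene
FOXR2	oncogene
TTYH1	oncogene
TERT	oncogene
MYC	oncogene
MYCN	oncogene
CTNNB1	oncogene
RELA	oncogene
YAP1	oncogene
MN1	oncogene
EWSR1	oncogene
TP53	tumor_suppressor
BCOR	tumor_suppressor
QKI	tumor_suppressor
NF1	tumor_suppressor
NF2	tumor_suppressor
CDKN2A	tumor_suppressor
CDKN2B	tumor_suppressor
ATRX	tumor_suppressor
SMARCB1	tumor_suppressor
FOXR2	transcription_factor
MYB	transcription_factor
MYBL1	transcription_factor
FLI1	transcription_factor
RELA	transcription_factor
CIC	transcription_factor
TP53	cosmic
BRAF	cosmic
EGFR	cosmic
EWSR1	cosmic
IDH1	cosmic
KIAA1549--BRAF	tcga_fusion
C11orf95--RELA	tcga_fusion
EWSR1--FLI1	tcga_fusion
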