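participant_id	biospecimen_id	phase_of_therapy	composition	cancer_predisposition	tmb	molecular_subtype
PT_0SPKM4S8	BS_VW4XN9Y7	initial CNS tumor	solid tissue	none documented	187.4	HGG, H3 wild type, TP53 activated
PT_3CHB9PK5	BS_20TBZG09	initial CNS tumor	solid tissue	CMMRD	307	HGG, H3 wild type, TP53 loss
PT_3CHB9PK5	BS_8AY2GM4G	progressive	solid tissue	CMMRD	321.6	HGG, H3 wild type, TP53 loss
PT_EB0D3BXG	BS_F0GNWEJJ	progressive	solid tissue	none documented	26.3	metastatic NBL, MYCN non-amplified
PT_JNEV57VK	BS_85Q5P8GF	initial CNS tumor	solid tissue	Lynch syndrome	4.7	DMG, H3 K28, TP53 loss
PT_JNEV57VK	BS_HM5GFJN8	progressive	derived cell line	Lynch syndrome	35.9	DMG, H3 K28, TP53 loss
PT_JNEV57VK	BS_QWM9BPDY	progressive	derived cell line	Lynch syndrome	7.4	DMG, H3 K28, TP53 loss
PT_JNEV57VK	BS_P0QJ1QAH	progressive	solid tissue	Lynch syndrome	6.3	DMG, H3 K28, TP53 activated
PT_S0Q27J13	BS_P3PF53V8	initial CNS tumor	solid tissue	none documented	15.5	HGG, H3 wild type, TP53 activated
PT_VTM2STE3	BS_ERFMPQN3	progressive	derived cell line	Lynch syndrome	5.7	HGG, H3 wild type, TP53 loss
PT_VTM2STE3	BS_02YBZSBY	progressive	solid tissue	Lynch syndrome	274.5	HGG, H3 wild type, TP53 activated
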