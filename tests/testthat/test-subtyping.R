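test_that("HGG rules fire in order with first match winning", {
  expect_equal(subtype_hgg(ev(snvs = snv_ev("H3F3A", "p.K28M", 28)))$
                 molecular_subtype, "DMG, H3 K28")
  expect_equal(subtype_hgg(ev(snvs = dplyr::bind_rows(
    snv_ev("HIST1H3B", "p.K28M", 28), snv_ev("BRAF", "p.V600E", 600)
  )))$molecular_subtype, "DMG, H3 K28, BRAF V600E")
  expect_equal(subtype_hgg(ev(snvs = snv_ev("H3F3A", "p.G35R", 35)))$
                 molecular_subtype, "HGG, H3 G35")
  expect_equal(subtype_hgg(ev(snvs = snv_ev("IDH1", "p.R132H", 132)))$
                 molecular_subtype, "HGG, IDH")
  expect_equal(subtype_hgg(ev(snvs = snv_ev("BRAF", "p.V600E", 600)))$
                 molecular_subtype, "HGG, BRAF V600E")
  expect_equal(subtype_hgg(ev())$molecular_subtype, "HGG, H3 wild type")
})

test_that("adding BRAF V600E to an H3F3A K28M sample never changes the label", {
  without <- subtype_hgg(ev(snvs = snv_ev("H3F3A", "p.K28M", 28)))
  with_braf <- subtype_hgg(ev(snvs = dplyr::bind_rows(
    snv_ev("H3F3A", "p.K28M", 28), snv_ev("BRAF", "p.V600E", 600)
  )))
  expect_equal(with_braf$molecular_subtype, without$molecular_subtype)
})

test_that("LGG rules comma-join in rule order with SEGA/GNT recoding and assay fallbacks", {
  lgg <- function(...) subtype_lgg_gnt(ev(...))$molecular_subtype
  expect_equal(lgg(fusions = fusion_ev("KIAA1549--BRAF")),
               "LGG, KIAA1549-BRAF")
  expect_equal(
    lgg(snvs = snv_ev("BRAF", "p.V600E", 600, domain = "PK_Tyr_Ser-Thr"),
        focal_cn = tibble::tibble(gene = "CDKN2A",
                                  status = "deep deletion")),
    "LGG, BRAF V600E, CDKN2A/B"
  )
  expect_equal(lgg(snvs = snv_ev("NF1", "p.R1000*", 1000)),
               "LGG, NF1-somatic")
  expect_equal(lgg(cancer_predispositions = "NF-1"), "LGG, NF1-germline")
  expect_equal(lgg(snvs = snv_ev("KRAS", "p.G12D", 12)), "LGG, other MAPK")
  expect_equal(lgg(fusions = fusion_ev("ETV6--NTRK2")), "LGG, RTK")
  expect_equal(lgg(snvs = snv_ev("FGFR1", "p.N546K", 546)), "LGG, FGFR")
  expect_equal(lgg(fusions = fusion_ev("MYB--QKI")), "LGG, MYB/MYBL1")
  expect_equal(lgg(), "LGG, wild type")
  expect_equal(lgg(has_rna = FALSE), "LGG, To be classified")
  expect_equal(
    subtype_lgg_gnt(ev(pathology_diagnosis =
      "Subependymal Giant Cell Astrocytoma (SEGA)"))$molecular_subtype,
    "SEGA, wild type"
  )
  expect_equal(
    subtype_lgg_gnt(ev(pathology_diagnosis = "Ganglioglioma",
                       pathology_free_text = "glioneuronal tumor",
                       fusions = fusion_ev("KIAA1549--BRAF")))$
      molecular_subtype,
    "GNT, KIAA1549-BRAF"
  )
})

test_that("embryonal rules resolve ETMR, HGNET, NB-FOXR2 and EFT-CIC branches", {
  z_hi <- c(LIN28A = 4)
  etmr <- ev(fusions = fusion_ev("TTYH1--C19MC"), expression_z = z_hi,
             focal_cn = tibble::tibble(gene = "C19MC",
                                       status = "amplification"))
  expect_equal(subtype_embryonal(etmr)$molecular_subtype,
               "ETMR, C19MC altered")
  nos <- ev(fusions = fusion_ev("TTYH1--C19MC"), expression_z = z_hi)
  expect_equal(subtype_embryonal(nos)$molecular_subtype, "ETMR, NOS")
  expect_equal(subtype_embryonal(ev(fusions = fusion_ev("MN1--BEND2")))$
                 molecular_subtype, "CNS HGNET-MN1")
  expect_equal(subtype_embryonal(ev(bcor_itd = TRUE))$molecular_subtype,
               "CNS HGNET-BCOR")
  expect_equal(subtype_embryonal(ev(expression_z = c(FOXR2 = 5)))$
                 molecular_subtype, "CNS NB-FOXR2")
  expect_equal(subtype_embryonal(ev(fusions = fusion_ev("CIC--NUTM1")))$
                 molecular_subtype, "CNS EFT-CIC")
  expect_equal(subtype_embryonal(ev())$molecular_subtype,
               "CNS embryonal, NOS")
  # eligibility: MN1::PATZ1 alone does not qualify
  expect_false(embryonal_eligible(ev(fusions = fusion_ev("MN1--PATZ1"))))
  expect_true(embryonal_eligible(ev(fusions = fusion_ev("MN1--BEND2"))))
  expect_true(embryonal_eligible(
    ev(pathology_diagnosis = "Supratentorial or Spinal Cord PNET")
  ))
})

test_that("EPN exclusive tier wins and non-exclusive evidence is counted", {
  expect_equal(subtype_epn(ev(fusions = fusion_ev("C11orf95--RELA")))$
                 molecular_subtype, "EPN, ST RELA")
  expect_equal(subtype_epn(ev(fusions = fusion_ev("YAP1--MAMLD1")))$
                 molecular_subtype, "EPN, ST YAP1")
  expect_equal(subtype_epn(ev(expression_z = c(CXorf67 = 3.5)))$
                 molecular_subtype, "EPN, PF A")
  # z of exactly 3 does not pass the "over 3" rule
  expect_equal(subtype_epn(ev(expression_z = c(CXorf67 = 3)))$
                 molecular_subtype, "EPN, To be classified")
  pfb <- ev(expression_z = c(IFT46 = 4),
            arm_events = tibble::tibble(arm = "6q", status = "loss"))
  expect_equal(subtype_epn(pfb)$molecular_subtype, "EPN, PF B")
  # non-exclusive: evidence for both sides is recorded, ties unresolved
  both <- subtype_epn(ev(expression_z = c(L1CAM = 4, CLDN1 = 4)))
  expect_equal(both$evidence_counts, c(st_rela = 1L, st_yap1 = 1L))
  expect_equal(both$molecular_subtype, "EPN, To be classified")
  rela_lean <- subtype_epn(ev(
    expression_z = c(L1CAM = 4),
    arm_events = tibble::tibble(arm = "9q", status = "loss")
  ))
  expect_equal(rela_lean$evidence_counts[["st_rela"]], 2L)
  expect_equal(rela_lean$molecular_subtype, "EPN, ST RELA")
})

test_that("CRANIO, neurocytoma and EWS calls follow age, site and fusion rules", {
  expect_equal(subtype_cranio(ev(age_years = 45,
                                 snvs = snv_ev("BRAF", "p.V600E", 600)))$
                 molecular_subtype, "CRANIO, PAP")
  expect_equal(subtype_cranio(ev(age_years = 10,
                                 snvs = snv_ev("CTNNB1", "p.S37F", 37,
                                               domain = "exon3")))$
                 molecular_subtype, "CRANIO, ADAM")
  # age exactly 40 fires neither rule
  expect_equal(subtype_cranio(ev(age_years = 40,
                                 snvs = snv_ev("BRAF", "p.V600E", 600)))$
                 molecular_subtype, "CRANIO, To be classified")
  expect_equal(subtype_neurocytoma(ev(primary_site = "Ventricles"))$
                 molecular_subtype, "CNC")
  expect_equal(subtype_neurocytoma(ev(primary_site = "Frontal Lobe"))$
                 molecular_subtype, "EVN")
  expect_equal(subtype_ews(ev(fusions = fusion_ev("EWSR1--FLI1")))$
                 molecular_subtype, "EWS")
  expect_null(subtype_ews(ev()))
})

test_that("MB consensus requires classifier agreement", {
  expect_equal(consensus_mb("SHH", "SHH")$molecular_subtype, "MB, SHH")
  expect_equal(consensus_mb("WNT", "WNT")$molecular_subtype, "MB, WNT")
  expect_equal(consensus_mb("Group3", "Group 3")$molecular_subtype,
               "MB, group 3")
  expect_equal(consensus_mb("Group3", "Group4")$molecular_subtype,
               "MB, To be classified")
  expect_equal(consensus_mb(NA, "SHH")$molecular_subtype,
               "MB, To be classified")
})

test_that("TP53 status distinguishes activated, lost and other", {
  expect_equal(annotate_tp53(ev(snvs = snv_ev("TP53", "p.R273C", 273,
                                              hotspot = TRUE,
                                              domain = "DNA-binding"))),
               "activated")
  expect_equal(annotate_tp53(ev(snvs = snv_ev("TP53", "p.R175H", 175,
                                              hotspot = TRUE,
                                              domain = "DNA-binding"))),
               "lost")
  # two alterations imply probable biallelic loss
  expect_equal(annotate_tp53(ev(
    snvs = snv_ev("TP53", "p.A347T", 347),
    focal_cn = tibble::tibble(gene = "TP53", status = "deep deletion")
  )), "lost")
  # a single SNV outside the DNA-binding domain stays "other"
  expect_equal(annotate_tp53(ev(snvs = snv_ev("TP53", "p.A347T", 347))),
               "other")
  # LFS predisposition alone implies a germline hit
  expect_equal(annotate_tp53(ev(cancer_predispositions = "LFS")), "lost")
  expect_equal(annotate_tp53(ev()), "other")
})

test_that("TP53 suffixes apply to HGG/DMG labels only and conflicts error", {
  calls <- tibble::tibble(
    sample_id = c("A", "B", "C"),
    molecular_subtype = c("DMG, H3 K28", "HGG, H3 wild type",
                          "LGG, KIAA1549-BRAF"),
    engine = c("HGG", "HGG", "LGG"), rule_trace = "t"
  )
  tp53 <- tibble::tibble(sample_id = c("A", "B", "C"),
                         tp53_status = c("lost", "other", "lost"))
  hist <- tibble::tibble(sample_id = c("A", "B", "C"))
  out <- integrate_subtypes(calls, tp53, hist)
  expect_equal(out$molecular_subtype,
               c("DMG, H3 K28, TP53 loss", "HGG, H3 wild type",
                 "LGG, KIAA1549-BRAF"))
  conflicting <- dplyr::bind_rows(calls, dplyr::mutate(
    calls[1, ], molecular_subtype = "HGG, IDH", rule_trace = "u"
  ))
  expect_error(integrate_subtypes(conflicting, tp53, hist), "conflicting")
})

test_that("engine calls are deterministic and traces replay to the same label", {
  e <- ev(snvs = dplyr::bind_rows(snv_ev("H3F3A", "p.K28M", 28),
                                  snv_ev("TP53", "p.R175H", 175,
                                         hotspot = TRUE,
                                         domain = "DNA-binding")))
  first <- subtype_hgg(e)
  replay <- subtype_hgg(e)
  expect_identical(first, replay)
  expect_equal(first$rule_trace, "hgg-1")
})
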