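#' @name subtyping
#' @title Rule-based molecular subtyping
#'
#' @description
#' The subtyping engine assigns research-grade molecular subtypes from
#' WHO-2016-aligned rule lists, one engine per eligible histology. Every
#' engine consumes a [subtype_evidence()] object and returns a call holding
#' the label and the ordered trace of rules that fired; [assign_subtypes()]
#' routes samples to engines by pathology and [integrate_subtypes()] merges
#' the calls (with TP53 status suffixes for high-grade gliomas) back into
#' the histology table.
NULL

subtype_call <- function(e, label, trace, engine) {
  list(sample_id = e$sample_id, molecular_subtype = label,
       rule_trace = trace, engine = engine)
}

HIST_K28_GENES <- c("HIST1H3B", "HIST1H3C", "HIST2H3C")

#' High-grade glioma subtyping
#'
#' Rules evaluated in order, first match wins:
#' histone H3 K28M in H3F3A (or in HIST1H3B/HIST1H3C/HIST2H3C without BRAF
#' V600E) defines "DMG, H3 K28"; HIST-gene K28M with BRAF V600E defines
#' "DMG, H3 K28, BRAF V600E"; H3F3A G35V/G35R defines "HGG, H3 G35"; IDH1
#' R132 defines "HGG, IDH"; BRAF V600E without a defining histone mutation
#' defines "HGG, BRAF V600E"; everything else is "HGG, H3 wild type".
#'
#' @param e A [subtype_evidence()] object.
#' @return A subtype call (list with `molecular_subtype` and `rule_trace`).
#' @export
subtype_hgg <- function(e) {
  braf_v600e <- has_snv(e, "BRAF", "p.V600E")
  h3f3a_k28 <- has_snv(e, "H3F3A", "p.K28M")
  hist_k28 <- has_snv(e, HIST_K28_GENES, "p.K28M")
  if (h3f3a_k28 || (hist_k28 && !braf_v600e)) {
    return(subtype_call(e, "DMG, H3 K28", "hgg-1", "HGG"))
  }
  if (hist_k28 && braf_v600e) {
    return(subtype_call(e, "DMG, H3 K28, BRAF V600E", "hgg-2", "HGG"))
  }
  if (has_snv(e, "H3F3A", c("p.G35V", "p.G35R"))) {
    return(subtype_call(e, "HGG, H3 G35", "hgg-3", "HGG"))
  }
  if (has_snv_prefix(e, "IDH1", "p.R132")) {
    return(subtype_call(e, "HGG, IDH", "hgg-4", "HGG"))
  }
  if (braf_v600e) {
    return(subtype_call(e, "HGG, BRAF V600E", "hgg-5", "HGG"))
  }
  subtype_call(e, "HGG, H3 wild type", "hgg-6", "HGG")
}

#' Low-grade glioma / glial-neuronal tumor subtyping
#'
#' Evaluates all eleven alteration rules; unlike the other engines, every
#' matching rule contributes and the matched parts are comma-joined in rule
#' order (e.g. "LGG, BRAF V600E, CDKN2A/B"). With no match, samples having
#' both DNA and RNA assays are "LGG, wild type" and samples missing an
#' assay are "LGG, To be classified". A SEGA pathology diagnosis recodes
#' the LGG prefix to SEGA; desmoplastic-infantile/glioneuronal free-text
#' diagnoses recode it to GNT.
#'
#' @inheritParams subtype_hgg
#' @return A subtype call.
#' @export
subtype_lgg_gnt <- function(e) {
  parts <- character(0)
  trace <- character(0)
  add <- function(cond, part, rule) {
    if (cond) {
      parts <<- c(parts, part)
      trace <<- c(trace, rule)
    }
  }
  braf_fusions <- e$fusions[e$fusions$gene5 == "BRAF" |
                              e$fusions$gene3 == "BRAF", , drop = FALSE]
  add(has_snv(e, "NF1"), "NF1-somatic", "lgg-1")
  add(any(grepl("NF-?1|[Nn]eurofibromatosis", e$cancer_predispositions)),
      "NF1-germline", "lgg-2")
  add(has_snv_prefix(e, "IDH1", "p.R132"), "IDH", "lgg-3")
  add(has_snv(e, c("H3F3A", "H3F3B", HIST_K28_GENES), "p.K28M") ||
        has_snv(e, "H3F3A", c("p.G35R", "p.G35V")), "H3", "lgg-4")
  add(has_snv(e, "BRAF", "p.V600E") ||
        has_snv_in_domain(e, "BRAF", "PK_Tyr_Ser-Thr"),
      "BRAF V600E", "lgg-5")
  add(has_fusion(e, "KIAA1549--BRAF"), "KIAA1549-BRAF", "lgg-6")
  braf_non_kinase <- {
    rows <- e$snvs[!is.na(e$snvs$gene) & e$snvs$gene == "BRAF", ,
                   drop = FALSE]
    any(is.na(rows$domain) | rows$domain != "PK_Tyr_Ser-Thr") &&
      !has_snv(e, "BRAF", "p.V600E")
  }
  add(has_snv(e, c("KRAS", "NRAS", "HRAS", "MAP2K1", "MAP2K2", "ARAF",
                   "RAF1")) ||
        braf_non_kinase ||
        has_fusion_partner(e, "RAF1") ||
        (nrow(braf_fusions) > 0 &&
           !all(braf_fusions$fusion_name == "KIAA1549--BRAF")),
      "other MAPK", "lgg-7")
  add(has_snv(e, c("MET", "KIT", "PDGFRA")) ||
        has_fusion_partner(e, c("ALK", "ROS1", "NTRK1", "NTRK2", "NTRK3",
                                "PDGFRA")),
      "RTK", "lgg-8")
  add(has_snv(e, "FGFR1", c("p.N546K", "p.K656E")) ||
        has_snv_prefix(e, "FGFR1", "p.N577") ||
        has_snv_prefix(e, "FGFR1", "p.K687") ||
        has_fusion_partner(e, c("FGFR1", "FGFR2")),
      "FGFR", "lgg-9")
  add(has_fusion_partner(e, c("MYB", "MYBL1")), "MYB/MYBL1", "lgg-10")
  add(has_focal(e, c("CDKN2A", "CDKN2B"), c("deep deletion", "loss")),
      "CDKN2A/B", "lgg-11")
  if (length(parts) == 0) {
    if (e$has_dna && e$has_rna) {
      parts <- "wild type"
      trace <- "lgg-wildtype"
    } else {
      parts <- "To be classified"
      trace <- "lgg-missing-assay"
    }
  }
  label <- paste0("LGG, ", paste(parts, collapse = ", "))
  if (!is.na(e$pathology_diagnosis) &&
      grepl("SEGA|Subependymal Giant Cell", e$pathology_diagnosis,
            ignore.case = TRUE)) {
    label <- sub("^LGG", "SEGA", label)
    trace <- c(trace, "lgg-sega-recode")
  } else if (!is.na(e$pathology_free_text) &&
             grepl("desmoplastic infantile|glioneuronal",
                   e$pathology_free_text, ignore.case = TRUE) &&
             (is.na(e$pathology_diagnosis) ||
                grepl("Low-grade glioma|Ganglioglioma",
                      e$pathology_diagnosis, ignore.case = TRUE))) {
    label <- sub("^LGG", "GNT", label)
    trace <- c(trace, "lgg-gnt-recode")
  }
  subtype_call(e, label, trace, "LGG")
}

# genes adjacent to or within the chromosome 19 miRNA cluster, used to
# qualify TTYH1 fusion partners for the ETMR rules
C19MC_PARTNERS <- c("C19MC", "MIR512-1", "MIR517A", "MIR519A1", "MIR520A")

#' Eligibility for non-MB, non-ATRT embryonal subtyping
#'
#' A sample enters embryonal subtyping when it has a TTYH1 5' fusion, an
#' MN1 5' fusion other than MN1::PATZ1, a PNET/ETMR pathology diagnosis, a
#' CNS (non-peripheral, non-metastatic) neuroblastoma diagnosis, or one of
#' the recognized embryonal free-text diagnoses.
#'
#' @inheritParams subtype_hgg
#' @return Logical.
#' @export
embryonal_eligible <- function(e) {
  mn1_fusions <- e$fusions[e$fusions$gene5 == "MN1", , drop = FALSE]
  free_text_hits <- c("embryonal tumor with multilayer rosettes",
                      "embryonal tumor, nos, congenital type",
                      "ependymoblastoma", "medulloepithelioma")
  has_fusion_partner(e, "TTYH1", role = "5prime") ||
    (nrow(mn1_fusions) > 0 &&
       !all(mn1_fusions$fusion_name == "MN1--PATZ1")) ||
    (!is.na(e$pathology_diagnosis) && e$pathology_diagnosis %in%
       c("Supratentorial or Spinal Cord PNET",
         "Embryonal Tumor with Multilayered Rosettes")) ||
    (!is.na(e$pathology_diagnosis) &&
       e$pathology_diagnosis == "Neuroblastoma" &&
       (is.na(e$primary_site) ||
          !grepl("peripheral|metasta", e$primary_site, ignore.case = TRUE))) ||
    (!is.na(e$pathology_free_text) &&
       any(vapply(free_text_hits, grepl, logical(1),
                  x = tolower(e$pathology_free_text), fixed = TRUE)))
}

#' Non-MB, non-ATRT embryonal tumor subtyping
#'
#' First match wins: ETMR C19MC-altered (LIN28A overexpression plus a TTYH1
#' 5' fusion with a C19MC-adjacent partner plus C19MC amplification), ETMR
#' NOS (same without the amplification), CNS HGNET-MN1 (MN1::BEND2 or
#' MN1::CXXC5), CNS HGNET-BCOR (BCOR internal tandem duplication), CNS
#' NB-FOXR2 (FOXR2 overexpression and/or fusion), CNS EFT-CIC (CIC
#' fusions), else CNS embryonal NOS. Overexpression means a cohort
#' z-score above 3.
#'
#' @inheritParams subtype_hgg
#' @return A subtype call.
#' @export
subtype_embryonal <- function(e) {
  ttyh1_c19mc <- any(e$fusions$gene5 == "TTYH1" &
                       e$fusions$gene3 %in% C19MC_PARTNERS)
  lin28a <- overexpressed(e, "LIN28A")
  c19mc_amp <- has_focal(e, "C19MC", c("amplification", "gain"))
  if (lin28a && ttyh1_c19mc && c19mc_amp) {
    return(subtype_call(e, "ETMR, C19MC altered", "emb-1", "EMB"))
  }
  if (lin28a && ttyh1_c19mc) {
    return(subtype_call(e, "ETMR, NOS", "emb-2", "EMB"))
  }
  if (has_fusion(e, c("MN1--BEND2", "MN1--CXXC5"))) {
    return(subtype_call(e, "CNS HGNET-MN1", "emb-3", "EMB"))
  }
  if (e$bcor_itd) {
    return(subtype_call(e, "CNS HGNET-BCOR", "emb-4", "EMB"))
  }
  if (overexpressed(e, "FOXR2") || has_fusion_partner(e, "FOXR2")) {
    return(subtype_call(e, "CNS NB-FOXR2", "emb-5", "EMB"))
  }
  if (has_fusion_partner(e, "CIC")) {
    return(subtype_call(e, "CNS EFT-CIC", "emb-6", "EMB"))
  }
  subtype_call(e, "CNS embryonal, NOS", "emb-7", "EMB")
}

#' Ependymoma subtyping
#'
#' An exclusive tier is checked first: any RELA fusion partner (ST RELA),
#' any YAP1 fusion partner (ST YAP1), posterior fossa A (CXorf67 z > 3, or
#' TKTL1 z > 3 with 1q gain) and posterior fossa B (GPBP17 or IFT46 z > 3
#' with 6p or 6q loss). Samples without exclusive evidence accumulate
#' non-exclusive flags for ST RELA (PTEN::TAS2R1 fusion, 9p/9q loss, RELA
#' or L1CAM z > 3) and ST YAP1 (C11orf95::MAML2 fusion, 11p loss, 11q
#' gain, ARL4D or CLDN1 z > 3); both flags can be present at once, so the
#' primary label follows the larger evidence count and ties (or no
#' evidence) fall back to "EPN, To be classified". The raw flag counts are
#' returned alongside the call.
#'
#' @inheritParams subtype_hgg
#' @return A subtype call with an extra `evidence_counts` element.
#' @export
subtype_epn <- function(e) {
  if (has_fusion_partner(e, "RELA")) {
    out <- subtype_call(e, "EPN, ST RELA", "epn-excl-rela", "EPN")
    out$evidence_counts <- c(st_rela = NA_integer_, st_yap1 = NA_integer_)
    return(out)
  }
  if (has_fusion_partner(e, "YAP1")) {
    out <- subtype_call(e, "EPN, ST YAP1", "epn-excl-yap1", "EPN")
    out$evidence_counts <- c(st_rela = NA_integer_, st_yap1 = NA_integer_)
    return(out)
  }
  if (overexpressed(e, "CXorf67") ||
      (overexpressed(e, "TKTL1") && has_arm(e, "1q", "gain"))) {
    out <- subtype_call(e, "EPN, PF A", "epn-excl-pfa", "EPN")
    out$evidence_counts <- c(st_rela = NA_integer_, st_yap1 = NA_integer_)
    return(out)
  }
  loss_6 <- has_arm(e, c("6p", "6q"), "loss")
  if ((overexpressed(e, "GPBP17") && loss_6) ||
      (overexpressed(e, "IFT46") && loss_6)) {
    out <- subtype_call(e, "EPN, PF B", "epn-excl-pfb", "EPN")
    out$evidence_counts <- c(st_rela = NA_integer_, st_yap1 = NA_integer_)
    return(out)
  }
  rela_flags <- c(
    fusion = has_fusion(e, "PTEN--TAS2R1"),
    arm9 = has_arm(e, c("9p", "9q"), "loss"),
    rela_z = overexpressed(e, "RELA"),
    l1cam_z = overexpressed(e, "L1CAM")
  )
  yap1_flags <- c(
    fusion = has_fusion(e, "C11orf95--MAML2"),
    arm11p = has_arm(e, "11p", "loss"),
    arm11q = has_arm(e, "11q", "gain"),
    arl4d_z = overexpressed(e, "ARL4D"),
    cldn1_z = overexpressed(e, "CLDN1")
  )
  n_rela <- sum(rela_flags)
  n_yap1 <- sum(yap1_flags)
  label <- if (n_rela == 0 && n_yap1 == 0) {
    "EPN, To be classified"
  } else if (n_rela > n_yap1) {
    "EPN, ST RELA"
  } else if (n_yap1 > n_rela) {
    "EPN, ST YAP1"
  } else {
    "EPN, To be classified"
  }
  out <- subtype_call(
    e, label,
    c("epn-nonexclusive",
      names(rela_flags)[rela_flags], names(yap1_flags)[yap1_flags]),
    "EPN"
  )
  out$evidence_counts <- c(st_rela = n_rela, st_yap1 = n_yap1)
  out
}

#' Craniopharyngioma subtyping
#'
#' Papillary (CRANIO, PAP) for patients over 40 with a BRAF V600E mutation;
#' adamantinomatous (CRANIO, ADAM) for patients younger than 40 with a
#' CTNNB1 exon-3 mutation; everything else — including age exactly 40,
#' which neither rule covers — is "CRANIO, To be classified".
#'
#' @inheritParams subtype_hgg
#' @return A subtype call.
#' @export
subtype_cranio <- function(e) {
  ctnnb1_ex3 <- has_snv_in_domain(e, "CTNNB1", "exon3")
  if (!is.na(e$age_years) && e$age_years > 40 &&
      has_snv(e, "BRAF", "p.V600E")) {
    return(subtype_call(e, "CRANIO, PAP", "cranio-1", "CRANIO"))
  }
  if (!is.na(e$age_years) && e$age_years < 40 && ctnnb1_ex3) {
    return(subtype_call(e, "CRANIO, ADAM", "cranio-2", "CRANIO"))
  }
  subtype_call(e, "CRANIO, To be classified", "cranio-3", "CRANIO")
}

#' Neurocytoma subtyping
#'
#' Central neurocytoma (CNC) when the tumor's primary site is the
#' ventricles, extraventricular neurocytoma (EVN) otherwise.
#'
#' @inheritParams subtype_hgg
#' @return A subtype call.
#' @export
subtype_neurocytoma <- function(e) {
  if (!is.na(e$primary_site) &&
      grepl("ventricles", e$primary_site, ignore.case = TRUE)) {
    return(subtype_call(e, "CNC", "nc-ventricles", "NC"))
  }
  subtype_call(e, "EVN", "nc-other-site", "NC")
}

#' Ewing sarcoma call
#'
#' Any tumor with an EWSR1 fusion, or an Ewing sarcoma pathology diagnosis,
#' is labelled EWS.
#'
#' @inheritParams subtype_hgg
#' @return A subtype call, or `NULL` when neither criterion holds.
#' @export
subtype_ews <- function(e) {
  if (has_fusion_partner(e, "EWSR1") ||
      (!is.na(e$pathology_diagnosis) &&
         grepl("Ewing", e$pathology_diagnosis, ignore.case = TRUE))) {
    return(subtype_call(e, "EWS", "ews-1", "EWS"))
  }
  NULL
}

#' Consensus of two medulloblastoma expression classifiers
#'
#' The medulloblastoma subtype is the consensus of two independent RNA
#' classifiers; when the two labels agree the shared subtype is emitted,
#' otherwise the sample is left "MB, To be classified".
#'
#' @param score1,score2 Classifier labels, each one of `WNT`, `SHH`,
#'   `Group3`/`Group 3`, `Group4`/`Group 4` (case-insensitive).
#' @param sample_id Optional sample identifier carried into the call.
#' @return A subtype call.
#' @export
consensus_mb <- function(score1, score2, sample_id = NA_character_) {
  norm <- function(x) {
    x <- gsub("[ _]", "", tolower(as.character(x)))
    dplyr::case_when(
      x == "wnt" ~ "WNT", x == "shh" ~ "SHH",
      x == "group3" ~ "group 3", x == "group4" ~ "group 4",
      TRUE ~ NA_character_
    )
  }
  a <- norm(score1)
  b <- norm(score2)
  label <- if (!is.na(a) && !is.na(b) && a == b) {
    paste0("MB, ", a)
  } else {
    "MB, To be classified"
  }
  list(sample_id = sample_id, molecular_subtype = label,
       rule_trace = if (startsWith(label, "MB, To be")) {
         "mb-disagree"
       } else {
         "mb-consensus"
       },
       engine = "MB")
}

#' TP53 alteration status
#'
#' "activated" for either of the two well-characterized gain-of-function
#' mutations p.R273C and p.R248W. "lost" for (i) a TP53 hotspot mutation,
#' (ii) two TP53 alterations of any kind (SNV, focal CNV, SV/fusion) —
#' probable biallelic loss, (iii) a single somatic alteration (an SNV
#' qualifies when it falls in the DNA-binding domain; a CNV loss or SV
#' always qualifies) or a germline TP53 mutation implied by a Li-Fraumeni
#' syndrome diagnosis, or (iv) an LFS diagnosis with a TP53 classifier
#' score above 0.5. Everything else is "other".
#'
#' @inheritParams subtype_hgg
#' @return One of `"activated"`, `"lost"`, `"other"`.
#' @export
annotate_tp53 <- function(e) {
  if (has_snv(e, "TP53", c("p.R273C", "p.R248W"))) {
    return("activated")
  }
  tp53_snvs <- e$snvs[!is.na(e$snvs$gene) & e$snvs$gene == "TP53", ,
                      drop = FALSE]
  tp53_cnv <- e$focal_cn[e$focal_cn$gene %in% "TP53" &
                           e$focal_cn$status %in%
                             c("loss", "deep deletion"), , drop = FALSE]
  tp53_sv <- e$fusions[e$fusions$gene5 %in% "TP53" |
                         e$fusions$gene3 %in% "TP53", , drop = FALSE]
  lfs <- e$germline_tp53_pathogenic ||
    any(grepl("LFS|Li-Fraumeni", e$cancer_predispositions,
              ignore.case = TRUE))
  n_alterations <- nrow(tp53_snvs) + nrow(tp53_cnv) + nrow(tp53_sv)
  hotspot_hit <- any(tidyr::replace_na(tp53_snvs$hotspot, FALSE))
  single_qualifying <- (nrow(tp53_snvs) >= 1 &&
                          any(!is.na(tp53_snvs$domain) &
                                tp53_snvs$domain == "DNA-binding")) ||
    nrow(tp53_cnv) >= 1 || nrow(tp53_sv) >= 1
  score <- e$classifier_scores$tp53_score %||% NA_real_
  if (hotspot_hit ||
      n_alterations >= 2 ||
      single_qualifying ||
      lfs ||
      (lfs && !is.na(score) && score > 0.5)) {
    return("lost")
  }
  "other"
}

#' Route samples to subtyping engines by pathology
#'
#' Dispatches each sample's evidence to the applicable engine: HGG/DIPG
#' diagnoses to [subtype_hgg()], LGG/ganglioglioma/SEGA to
#' [subtype_lgg_gnt()], medulloblastoma to [consensus_mb()], ependymoma to
#' [subtype_epn()], craniopharyngioma to [subtype_cranio()], neurocytoma
#' to [subtype_neurocytoma()], Ewing sarcoma (by diagnosis or EWSR1
#' fusion) to [subtype_ews()], and embryonal-eligible samples (see
#' [embryonal_eligible()]) to [subtype_embryonal()]. Samples matching no
#' engine are left unlabelled.
#'
#' @param evidence_list Named list of [subtype_evidence()] objects.
#' @return Tibble with `sample_id`, `molecular_subtype`, `engine`,
#'   `rule_trace` (rules joined by `";"`), one row per routed sample.
#' @export
assign_subtypes <- function(evidence_list) {
  calls <- list()
  for (e in evidence_list) {
    dx <- e$pathology_diagnosis
    call <- NULL
    ews <- subtype_ews(e)
    if (!is.null(ews) && !is.na(dx) &&
        grepl("Ewing|sarcoma", dx, ignore.case = TRUE)) {
      call <- ews
    } else if (!is.na(dx) &&
               grepl("High-grade glioma|Diffuse intrinsic pontine|Brainstem glioma",
                     dx, ignore.case = TRUE)) {
      call <- subtype_hgg(e)
    } else if (!is.na(dx) &&
               grepl("Low-grade glioma|Ganglioglioma|Subependymal Giant Cell",
                     dx, ignore.case = TRUE)) {
      call <- subtype_lgg_gnt(e)
    } else if (!is.na(dx) && grepl("Medulloblastoma", dx,
                                   ignore.case = TRUE)) {
      call <- consensus_mb(e$classifier_scores$mb_classifier_1 %||% NA,
                           e$classifier_scores$mb_classifier_2 %||% NA,
                           sample_id = e$sample_id)
    } else if (!is.na(dx) && grepl("Ependymoma", dx, ignore.case = TRUE)) {
      call <- subtype_epn(e)
    } else if (!is.na(dx) && grepl("Craniopharyngioma", dx,
                                   ignore.case = TRUE)) {
      call <- subtype_cranio(e)
    } else if (!is.na(dx) && grepl("Neurocytoma", dx, ignore.case = TRUE)) {
      call <- subtype_neurocytoma(e)
    } else if (embryonal_eligible(e)) {
      call <- subtype_embryonal(e)
    } else if (!is.null(ews)) {
      call <- ews
    }
    if (!is.null(call)) {
      calls[[length(calls) + 1]] <- tibble(
        sample_id = call$sample_id,
        molecular_subtype = call$molecular_subtype,
        engine = call$engine,
        rule_trace = paste(call$rule_trace, collapse = ";")
      )
    }
  }
  if (length(calls) == 0) {
    return(tibble(sample_id = character(), molecular_subtype = character(),
                  engine = character(), rule_trace = character()))
  }
  bind_rows(calls)
}

#' Integrate subtype calls and TP53 status into the histology table
#'
#' High-grade glioma labels (HGG/DMG prefixes) are suffixed with
#' ", TP53 loss" or ", TP53 activated" when the sample's TP53 status is
#' not "other"; labels from other engines are never suffixed. The
#' histology table gains a `molecular_subtype` column; in-scope samples
#' with no call keep `NA`. Two different labels for one sample are an
#' error, reported with both rule traces.
#'
#' @param calls Output of [assign_subtypes()].
#' @param tp53_status Tibble with `sample_id` and `tp53_status`
#'   (`activated`/`lost`/`other`), or `NULL`.
#' @param histology Histology tibble with a `sample_id` column.
#' @return `histology` with a `molecular_subtype` column added.
#' @export
integrate_subtypes <- function(calls, tp53_status = NULL, histology) {
  dup <- calls |>
    distinct(.data$sample_id, .data$molecular_subtype, .data$rule_trace) |>
    count(.data$sample_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    conflicts <- calls[calls$sample_id %in% dup$sample_id, , drop = FALSE]
    stop("conflicting subtype calls for sample(s): ",
         paste(unique(conflicts$sample_id), collapse = ", "), "\n",
         paste(conflicts$sample_id, conflicts$molecular_subtype,
               conflicts$rule_trace, sep = " | ", collapse = "\n"),
         call. = FALSE)
  }
  calls <- distinct(calls, .data$sample_id, .keep_all = TRUE)
  if (!is.null(tp53_status)) {
    calls <- calls |>
      left_join(tp53_status, by = "sample_id") |>
      mutate(molecular_subtype = ifelse(
        grepl("^(HGG|DMG)", .data$molecular_subtype) &
          !is.na(.data$tp53_status) & .data$tp53_status != "other",
        paste0(.data$molecular_subtype, ", TP53 ",
               ifelse(.data$tp53_status == "lost", "loss", "activated")),
        .data$molecular_subtype
      )) |>
      select(-"tp53_status")
  }
  histology |>
    left_join(calls |> select("sample_id", "molecular_subtype"),
              by = "sample_id")
}
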