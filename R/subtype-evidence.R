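#' Assemble the per-sample evidence consumed by the subtyping rules
#'
#' A `subtype_evidence` object aggregates, for one tumor sample, every input
#' any subtyping rule can reference: clinical fields, somatic SNVs with
#' protein change and domain, fusions with 5'/3' partners, focal
#' copy-number and arm-level events, expression z-scores, external
#' classifier scores, TMB and germline TP53 status.
#'
#' @param sample_id Sample identifier.
#' @param pathology_diagnosis,pathology_free_text,primary_site Clinical
#'   strings (may be `NA`).
#' @param age_years Age at diagnosis in years.
#' @param cancer_predispositions Character vector (e.g. `"LFS"`, `"NF-1"`).
#' @param snvs Tibble with `gene`, `protein_change` (e.g. `"p.K28M"`),
#'   `protein_position`, `hotspot`, `domain`.
#' @param fusions Tibble with `fusion_name`, `gene5`, `gene3`.
#' @param focal_cn Tibble with `gene`, `status` (`gain`, `loss`,
#'   `deep deletion`, `amplification`).
#' @param arm_events Tibble with `arm` (e.g. `"1q"`), `status`.
#' @param expression_z Named numeric vector of gene z-scores.
#' @param classifier_scores Named list; recognized names are `tp53_score`,
#'   `mb_classifier_1`, `mb_classifier_2`.
#' @param tmb Tumor mutation burden (Mut/Mb) or `NA`.
#' @param germline_tp53_pathogenic Pathogenic germline TP53 variant present.
#' @param bcor_itd BCOR internal tandem duplication detected (supplied as a
#'   boolean; its detection is an upstream concern).
#' @param has_dna,has_rna Assay availability, which decides between
#'   "wildtype" and "To be classified" fallbacks.
#' @return A list of class `subtype_evidence`.
#' @export
subtype_evidence <- function(sample_id,
                             pathology_diagnosis = NA_character_,
                             pathology_free_text = NA_character_,
                             primary_site = NA_character_,
                             age_years = NA_real_,
                             cancer_predispositions = character(0),
                             snvs = NULL, fusions = NULL, focal_cn = NULL,
                             arm_events = NULL,
                             expression_z = numeric(0),
                             classifier_scores = list(),
                             tmb = NA_real_,
                             germline_tp53_pathogenic = FALSE,
                             bcor_itd = FALSE,
                             has_dna = TRUE, has_rna = TRUE) {
  blank <- function(df, cols) {
    if (is.null(df)) {
      df <- as_tibble(stats::setNames(
        rep(list(character(0)), length(cols)), cols
      ))
    }
    for (col in setdiff(cols, names(df))) df[[col]] <- NA
    df
  }
  structure(list(
    sample_id = sample_id,
    pathology_diagnosis = pathology_diagnosis,
    pathology_free_text = pathology_free_text,
    primary_site = primary_site,
    age_years = age_years,
    cancer_predispositions = cancer_predispositions,
    snvs = blank(snvs, c("gene", "protein_change", "protein_position",
                         "hotspot", "domain")),
    fusions = blank(fusions, c("fusion_name", "gene5", "gene3")),
    focal_cn = blank(focal_cn, c("gene", "status")),
    arm_events = blank(arm_events, c("arm", "status")),
    expression_z = expression_z,
    classifier_scores = classifier_scores,
    tmb = tmb,
    germline_tp53_pathogenic = isTRUE(germline_tp53_pathogenic),
    bcor_itd = isTRUE(bcor_itd),
    has_dna = isTRUE(has_dna),
    has_rna = isTRUE(has_rna)
  ), class = "subtype_evidence")
}

#' @export
print.subtype_evidence <- function(x, ...) {
  cat("<subtype_evidence> sample", x$sample_id, "\n")
  cat("  diagnosis:", x$pathology_diagnosis, "\n")
  cat("  SNVs:", nrow(x$snvs), " fusions:", nrow(x$fusions),
      " focal CN:", nrow(x$focal_cn), " arm events:", nrow(x$arm_events),
      "\n")
  invisible(x)
}

# --- evidence predicates used by the rule lists ------------------------------

has_snv <- function(e, gene, change = NULL) {
  rows <- e$snvs[!is.na(e$snvs$gene) & e$snvs$gene %in% gene, , drop = FALSE]
  if (is.null(change)) {
    return(nrow(rows) > 0)
  }
  any(!is.na(rows$protein_change) & rows$protein_change %in% change)
}

# protein-change prefix match, e.g. "p.R132" matches p.R132H, p.R132C ...
has_snv_prefix <- function(e, gene, prefix) {
  rows <- e$snvs[!is.na(e$snvs$gene) & e$snvs$gene %in% gene, , drop = FALSE]
  any(!is.na(rows$protein_change) &
        startsWith(rows$protein_change, prefix))
}

has_snv_in_domain <- function(e, gene, domain) {
  rows <- e$snvs[!is.na(e$snvs$gene) & e$snvs$gene %in% gene, , drop = FALSE]
  any(!is.na(rows$domain) & rows$domain == domain)
}

has_fusion_partner <- function(e, gene, role = c("any", "5prime", "3prime")) {
  role <- match.arg(role)
  switch(role,
    any = any(e$fusions$gene5 %in% gene | e$fusions$gene3 %in% gene),
    `5prime` = any(e$fusions$gene5 %in% gene),
    `3prime` = any(e$fusions$gene3 %in% gene)
  )
}

has_fusion <- function(e, name) {
  any(e$fusions$fusion_name %in% name)
}

zscore_of <- function(e, gene) {
  z <- e$expression_z[gene]
  if (length(z) == 0 || is.na(z)) NA_real_ else unname(z)
}

overexpressed <- function(e, gene, threshold = 3) {
  z <- zscore_of(e, gene)
  !is.na(z) && z > threshold
}

has_focal <- function(e, gene, status) {
  any(e$focal_cn$gene %in% gene & e$focal_cn$status %in% status)
}

has_arm <- function(e, arm, status) {
  any(e$arm_events$arm %in% arm & e$arm_events$status %in% status)
}

# Minimal protein-domain annotation backing the domain-aware rules: the TP53
# DNA-binding domain and the BRAF protein-kinase domain by residue range,
# plus the CTNNB1 exon-3 degron region.
domain_for <- function(gene, protein_position) {
  dplyr::case_when(
    gene == "TP53" & !is.na(protein_position) &
      protein_position >= 102 & protein_position <= 292 ~ "DNA-binding",
    gene == "BRAF" & !is.na(protein_position) &
      protein_position >= 457 & protein_position <= 717 ~ "PK_Tyr_Ser-Thr",
    gene == "CTNNB1" & !is.na(protein_position) &
      protein_position >= 5 & protein_position <= 80 ~ "exon3",
    TRUE ~ NA_character_
  )
}

#' Build subtyping evidence from pipeline outputs
#'
#' Converts the outputs of the consensus-SNV, fusion-prioritization and
#' focal-copy-number stages, plus expression z-scores and metadata, into
#' one [subtype_evidence()] object per sample.
#'
#' @param histology Histology tibble; one row per sample with the clinical
#'   columns named in [subtype_evidence()] (`sample_id`,
#'   `pathology_diagnosis`, `pathology_free_text_diagnosis`,
#'   `primary_site`, `age_years`, `cancer_predispositions`,
#'   `experimental_strategy`, `RNA_library`).
#' @param snvs Consensus + hotspot-rescued variant calls.
#' @param fusions Prioritized fusion table.
#' @param focal Gene-level focal CN table with `sample_id` added, or `NULL`.
#' @param arm_events Tibble `sample_id`, `arm`, `status`, or `NULL`.
#' @param expression_z Genes-by-samples z-score matrix
#'   ([expression_zscore_matrix()]), or `NULL`.
#' @param classifier_scores Tibble `sample_id`, `tp53_score`,
#'   `mb_classifier_1`, `mb_classifier_2`, or `NULL`.
#' @param tmb Tibble `sample_id`, `tmb`, or `NULL`.
#' @param bcor_itd Character vector of samples with a BCOR internal tandem
#'   duplication.
#' @return Named list of `subtype_evidence` objects keyed by sample.
#' @export
build_subtype_evidence <- function(histology, snvs, fusions, focal = NULL,
                                   arm_events = NULL, expression_z = NULL,
                                   classifier_scores = NULL, tmb = NULL,
                                   bcor_itd = character(0)) {
  rna_samples <- histology$sample_id[
    !is.na(histology$experimental_strategy) &
      histology$experimental_strategy == "RNA-Seq"
  ]
  # RNA evidence belongs to the patient's tumor; map RNA aliquots onto the
  # DNA sample of the same specimen via the shared specimen column if given.
  get_col <- function(df, col, default = NA) {
    if (!is.null(df) && col %in% names(df)) df[[col]] else default
  }
  samples <- histology[is.na(get_col(histology, "sample_type")) |
                         get_col(histology, "sample_type") == "tumor", ,
                       drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(samples))) {
    row <- samples[i, ]
    sid <- row$sample_id
    snv_rows <- snvs[snvs$sample_id == sid, , drop = FALSE]
    ev_snvs <- tibble(
      gene = snv_rows$hugo_symbol,
      protein_change = snv_rows$hgvsp_short,
      protein_position = snv_rows$protein_position,
      hotspot = tidyr::replace_na(snv_rows$hotspot, FALSE),
      domain = domain_for(snv_rows$hugo_symbol, snv_rows$protein_position)
    )
    fus_rows <- fusions[fusions$sample_id == sid, , drop = FALSE]
    ev_fus <- tibble(fusion_name = fus_rows$fusion_name,
                     gene5 = fus_rows$gene5, gene3 = fus_rows$gene3)
    ev_focal <- NULL
    if (!is.null(focal)) {
      f <- focal[focal$sample_id == sid, , drop = FALSE]
      ev_focal <- tibble(gene = f$gene, status = f$status)
    }
    ev_arm <- NULL
    if (!is.null(arm_events)) {
      a <- arm_events[arm_events$sample_id == sid, , drop = FALSE]
      ev_arm <- tibble(arm = a$arm, status = a$status)
    }
    ez <- numeric(0)
    if (!is.null(expression_z) && sid %in% colnames(expression_z)) {
      ez <- expression_z[, sid]
    }
    cs <- list()
    if (!is.null(classifier_scores)) {
      c_row <- classifier_scores[classifier_scores$sample_id == sid, ,
                                 drop = FALSE]
      if (nrow(c_row) == 1) {
        cs <- as.list(c_row[, setdiff(names(c_row), "sample_id")])
      }
    }
    tmb_val <- NA_real_
    if (!is.null(tmb)) {
      t_row <- tmb[tmb$sample_id == sid, , drop = FALSE]
      if (nrow(t_row) >= 1) tmb_val <- t_row$tmb[1]
    }
    preds <- get_col(row, "cancer_predispositions", NA_character_)
    preds <- if (is.na(preds) || preds == "") {
      character(0)
    } else {
      strsplit(preds, ";", fixed = TRUE)[[1]]
    }
    out[[sid]] <- subtype_evidence(
      sample_id = sid,
      pathology_diagnosis = get_col(row, "pathology_diagnosis",
                                    NA_character_),
      pathology_free_text = get_col(row, "pathology_free_text_diagnosis",
                                    NA_character_),
      primary_site = get_col(row, "primary_site", NA_character_),
      age_years = get_col(row, "age_years", NA_real_),
      cancer_predispositions = preds,
      snvs = ev_snvs, fusions = ev_fus, focal_cn = ev_focal,
      arm_events = ev_arm, expression_z = ez, classifier_scores = cs,
      tmb = tmb_val,
      germline_tp53_pathogenic = "LFS" %in% preds,
      bcor_itd = sid %in% bcor_itd,
      has_dna = isTRUE(get_col(row, "has_dna", TRUE)),
      has_rna = isTRUE(get_col(row, "has_rna", sid %in% rna_samples ||
                                 length(ez) > 0))
    )
  }
  out
}
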