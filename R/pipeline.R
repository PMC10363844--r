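EXPRESSION_MARKER_GENES <- c("LIN28A", "FOXR2", "CXorf67", "TKTL1",
                             "GPBP17", "IFT46", "RELA", "L1CAM", "ARL4D",
                             "CLDN1")

#' Arm-level events and gene-level statuses for every sample
#'
#' Runs the cytoband/arm dominant-status resolution and the gene-level
#' copy-number classification per sample over a consensus segment table.
#'
#' @param consensus_cnv Final consensus segments (all samples).
#' @param cytobands Cytoband tibble.
#' @param gene_models Gene/exon interval tibble.
#' @return List with `arm_events` (tibble `sample_id`, `arm`, `status`,
#'   restricted to dominant gains/losses) and `gene_cn` (tibble
#'   `sample_id`, `gene`, `status`, `copy_number`).
#' @export
cnv_evidence_tables <- function(consensus_cnv, cytobands, gene_models) {
  samples <- unique(consensus_cnv$sample_id)
  arm_rows <- list()
  gene_rows <- list()
  for (s in samples) {
    seg <- consensus_cnv[consensus_cnv$sample_id == s, , drop = FALSE]
    arms <- band_status_fractions(seg, cytobands) |>
      arm_fractions() |>
      dominant_status()
    hit <- arms[arms$status %in% c("gain", "loss"), , drop = FALSE]
    if (nrow(hit) > 0) {
      arm_rows[[s]] <- tibble(sample_id = s, arm = hit$region,
                              status = hit$status)
    }
    genes <- gene_level_status(seg, gene_models)
    if (nrow(genes) > 0) {
      genes$sample_id <- s
      gene_rows[[s]] <- genes
    }
  }
  list(
    arm_events = if (length(arm_rows)) bind_rows(arm_rows) else
      tibble(sample_id = character(), arm = character(),
             status = character()),
    gene_cn = if (length(gene_rows)) bind_rows(gene_rows) else
      tibble(gene = character(), chromosome = character(),
             status = character(), copy_number = integer(),
             sample_id = character())
  )
}

#' Run every pipeline stage on a synthetic cohort
#'
#' Generates a cohort from the configuration, simulates the per-caller SNV,
#' CNV/SV and fusion/expression outputs, and runs the full downstream
#' pipeline: consensus SNV calling with hotspot rescue, consensus CNV
#' building with merge/exclusion/size filters, arm- and gene-level
#' copy-number resolution, expression collapsing and marker z-scores,
#' fusion standardization/filtering/prioritization, evidence assembly, the
#' subtyping engines, TP53 annotation and final label integration.
#'
#' @param config A [cohort_config()].
#' @return List with the cohort (`histology`, `truth`), the simulated
#'   caller tables, every intermediate result, and the final
#'   `integrated_histology` with its `molecular_subtype` column.
#' @export
run_synthetic_pipeline <- function(config) {
  cohort <- generate_cohort(config)
  histology <- cohort$histology
  truth <- cohort$truth
  snv_tables <- simulate_multicaller_snv(truth, config)
  cnv_tables <- simulate_multicaller_cnv(truth, config)
  fus_expr <- simulate_fusions_and_expression(truth, config, histology)

  snv_res <- consensus_snv(snv_tables$strelka2, snv_tables$mutect2,
                           snv_tables$lancet)
  snv_evidence <- bind_rows(snv_res$consensus, snv_res$hotspot)
  snv_evidence <- snv_evidence[!duplicated(variant_key(snv_evidence)), ,
                               drop = FALSE]

  filtered <- filter_caller_segments(cnv_tables$freec, cnv_tables$cnvkit,
                                     cnv_tables$manta)
  cons_cnv <- consensus_intervals(filtered)
  final_cnv <- merge_and_filter(cons_cnv, config$genome$exclusions)
  cnv_ev <- cnv_evidence_tables(final_cnv, config$genome$cytobands,
                                toy_gene_models())

  collapsed_fpkm <- collapse_to_symbols(fus_expr$fpkm)
  collapsed_tpm <- collapse_to_symbols(fus_expr$tpm)
  rna_samples <- histology$sample_id[histology$sample_type == "tumor" &
                                       histology$has_rna]
  zmat <- if (length(rna_samples) > 1) {
    expression_zscore_matrix(collapsed_fpkm, EXPRESSION_MARKER_GENES,
                             intersect(rna_samples,
                                       names(collapsed_fpkm)))
  } else {
    NULL
  }

  std_fusions <- standardize_fusion_calls(fus_expr$starfusion,
                                          fus_expr$arriba)
  kept_fusions <- filter_fusion_artifacts(std_fusions, collapsed_tpm)
  hist_map <- histology |>
    filter(.data$sample_type == "tumor") |>
    select("sample_id", "broad_histology")
  prioritized <- prioritize_fusions(kept_fusions, hist_map,
                                    read_driver_lists())

  classifier_scores <- truth$mb_scores
  classifier_scores$tp53_score <- NA_real_

  evidence <- build_subtype_evidence(
    histology, snv_evidence, prioritized,
    focal = cnv_ev$gene_cn, arm_events = cnv_ev$arm_events,
    expression_z = zmat, classifier_scores = classifier_scores,
    bcor_itd = truth$bcor_itd
  )
  subtype_calls <- assign_subtypes(evidence)
  tp53 <- tibble(
    sample_id = vapply(evidence, function(e) e$sample_id, character(1),
                       USE.NAMES = FALSE),
    tp53_status = vapply(evidence, annotate_tp53, character(1),
                         USE.NAMES = FALSE)
  )
  integrated <- integrate_subtypes(subtype_calls, tp53, histology)
  list(
    histology = histology, truth = truth,
    snv_tables = snv_tables, cnv_tables = cnv_tables,
    fusion_expression = fus_expr,
    consensus_snv = snv_res$consensus, hotspot_snv = snv_res$hotspot,
    snv_evidence = snv_evidence,
    consensus_cnv = final_cnv,
    arm_events = cnv_ev$arm_events, gene_cn = cnv_ev$gene_cn,
    collapsed_fpkm = collapsed_fpkm,
    expression_z = zmat,
    standardized_fusions = std_fusions,
    filtered_fusions = kept_fusions,
    prioritized_fusions = prioritized,
    evidence = evidence,
    subtype_calls = subtype_calls, tp53 = tp53,
    integrated_histology = integrated
  )
}
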