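#' Read driver-gene lists used for fusion annotation
#'
#' @param path Tab-separated file with columns `name` and `category`
#'   (`kinase`, `oncogene`, `tumor_suppressor`, `transcription_factor`,
#'   `cosmic`, `tcga_fusion`). Defaults to the synthetic list bundled with
#'   the package; the oncogene list includes MYBL1, SNCAIP, FOXR2, TTYH1 and
#'   TERT and the tumor-suppressor list includes BCOR and QKI, additions
#'   motivated by the pediatric cancer literature.
#' @return Named list of character vectors, one per category.
#' @export
read_driver_lists <- function(path = pedcns_extdata("synthetic_driver_genes.tsv")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  split(raw$name, raw$category)
}

normalize_frame <- function(x) {
  x <- tolower(as.character(x))
  dplyr::case_when(
    x %in% c("inframe", "in-frame", "in_frame") ~ "in-frame",
    x %in% c("frameshift", "out-of-frame", "out_of_frame") ~ "frameshift",
    TRUE ~ "other"
  )
}

#' Standardize two fusion callers' outputs into one schema
#'
#' Harmonizes the two caller dialects into the unified fusion-call schema:
#' one record per (sample, fusion name, caller), with read counts maximized
#' over duplicate rows and the reading frame normalized to
#' in-frame/frameshift/other. Rows that cannot be parsed (missing partner
#' genes or sample) are skipped and counted in a message.
#'
#' @param starfusion Tibble with columns `sample_id`, `FusionName`
#'   (`"GENE5--GENE3"`), `JunctionReadCount`, `SpanningFragCount`,
#'   `PROT_FUSION_TYPE`; or `NULL`.
#' @param arriba Tibble with columns `sample_id`, `gene1`, `gene2`,
#'   `split_reads1`, `split_reads2`, `discordant_mates`, `reading_frame`,
#'   `confidence`; or `NULL`.
#' @return Tibble of unified fusion calls: `sample_id`, `gene5`, `gene3`,
#'   `fusion_name`, `caller`, `frame`, `junction_reads`, `spanning_frags`,
#'   `caller_confidence`.
#' @export
standardize_fusion_calls <- function(starfusion = NULL, arriba = NULL) {
  skipped <- 0L
  parts <- list()
  if (!is.null(starfusion) && nrow(starfusion) > 0) {
    assert_columns(starfusion, c("sample_id", "FusionName",
                                 "JunctionReadCount", "SpanningFragCount"),
                   what = "starfusion table")
    genes <- stringr::str_split_fixed(starfusion$FusionName, "--", 2)
    sf <- tibble(
      sample_id = as.character(starfusion$sample_id),
      gene5 = genes[, 1], gene3 = genes[, 2],
      caller = "starfusion",
      frame = normalize_frame(starfusion$PROT_FUSION_TYPE %||% "other"),
      junction_reads = as.integer(starfusion$JunctionReadCount),
      spanning_frags = as.integer(starfusion$SpanningFragCount),
      caller_confidence = NA_character_
    )
    bad <- !nzchar(sf$gene5) | !nzchar(sf$gene3) | is.na(sf$sample_id)
    skipped <- skipped + sum(bad)
    parts$starfusion <- sf[!bad, , drop = FALSE]
  }
  if (!is.null(arriba) && nrow(arriba) > 0) {
    assert_columns(arriba, c("sample_id", "gene1", "gene2", "split_reads1",
                             "split_reads2", "discordant_mates"),
                   what = "arriba table")
    ar <- tibble(
      sample_id = as.character(arriba$sample_id),
      gene5 = as.character(arriba$gene1), gene3 = as.character(arriba$gene2),
      caller = "arriba",
      frame = normalize_frame(arriba$reading_frame %||% "other"),
      junction_reads = as.integer(arriba$split_reads1) +
        as.integer(arriba$split_reads2),
      spanning_frags = as.integer(arriba$discordant_mates),
      caller_confidence = if ("confidence" %in% names(arriba)) {
        as.character(arriba$confidence)
      } else {
        NA_character_
      }
    )
    bad <- is.na(ar$gene5) | is.na(ar$gene3) | !nzchar(ar$gene5) |
      !nzchar(ar$gene3) | is.na(ar$sample_id)
    skipped <- skipped + sum(bad)
    parts$arriba <- ar[!bad, , drop = FALSE]
  }
  if (skipped > 0) {
    message(skipped, " unparseable fusion row(s) skipped")
  }
  out <- bind_rows(parts)
  if (nrow(out) == 0) {
    return(tibble(
      sample_id = character(), gene5 = character(), gene3 = character(),
      fusion_name = character(), caller = character(), frame = character(),
      junction_reads = integer(), spanning_frags = integer(),
      caller_confidence = character()
    ))
  }
  out |>
    mutate(fusion_name = paste0(.data$gene5, "--", .data$gene3)) |>
    group_by(.data$sample_id, .data$fusion_name, .data$caller) |>
    summarise(
      gene5 = .data$gene5[1], gene3 = .data$gene3[1],
      frame = .data$frame[1],
      junction_reads = max(.data$junction_reads),
      spanning_frags = max(.data$spanning_frags),
      caller_confidence = .data$caller_confidence[1],
      .groups = "drop"
    ) |>
    select("sample_id", "gene5", "gene3", "fusion_name", "caller", "frame",
           "junction_reads", "spanning_frags", "caller_confidence") |>
    arrange(.data$sample_id, .data$fusion_name, .data$caller)
}

# TPM of a gene in a sample from a collapsed expression tibble; 0 if absent.
tpm_lookup <- function(tpm, genes, samples) {
  out <- numeric(length(genes))
  sample_cols <- setdiff(names(tpm), c("gene_id", "gene_symbol"))
  idx <- match(genes, tpm$gene_symbol)
  ok <- !is.na(idx) & samples %in% sample_cols
  if (any(ok)) {
    out[ok] <- as.numeric(as.matrix(
      tpm[, sample_cols, drop = FALSE]
    )[cbind(idx[ok], match(samples[ok], sample_cols))])
  }
  out
}

#' Remove artifact fusion calls
#'
#' Retains only in-frame and frameshift calls with at least one junction
#' read and at least one partner expressed (TPM > 1 in the matching
#' sample), and removes calls whose spanning-fragment count exceeds the
#' junction-read count by more than ten — a read-support pattern typical of
#' false positives. A partner absent from the expression matrix is treated
#' as unexpressed. The two conditions are applied together in one pass, so
#' the result does not depend on their order. Idempotent.
#'
#' @param calls Standardized fusion calls.
#' @param tpm Collapsed TPM expression tibble ([collapse_to_symbols()]).
#' @param max_spanning_excess Maximum allowed `spanning_frags -
#'   junction_reads` (default 10).
#' @return Filtered tibble, a subset of `calls`.
#' @export
filter_fusion_artifacts <- function(calls, tpm, max_spanning_excess = 10) {
  if (nrow(calls) == 0) {
    return(calls)
  }
  tpm5 <- tpm_lookup(tpm, calls$gene5, calls$sample_id)
  tpm3 <- tpm_lookup(tpm, calls$gene3, calls$sample_id)
  keep <- calls$frame %in% c("in-frame", "frameshift") &
    calls$junction_reads >= 1 &
    (tpm5 > 1 | tpm3 > 1) &
    (calls$spanning_frags - calls$junction_reads) <= max_spanning_excess
  calls[keep, , drop = FALSE]
}

#' Prioritize putative oncogenic fusions
#'
#' First removes promiscuous-partner calls: if a 5' or 3' gene fuses to more
#' than five distinct partner genes within one sample, all of that gene's
#' calls in the sample are removed as likely artifacts. The retained set is
#' then the union of (1) fusions detected by both callers in a sample, (2)
#' fusions recurrent within a broad histology grouping (more than two
#' samples), and (3) fusions specific to a single broad histology across
#' the cohort. Each retained fusion is flagged as a putative driver when
#' either partner appears in a kinase, oncogene, tumor-suppressor,
#' transcription-factor or COSMIC list, or the fusion itself is a known
#' TCGA fusion. Reciprocal fusions (A--B vs B--A) are distinct.
#'
#' @param calls Artifact-filtered fusion calls.
#' @param histology_map Tibble with `sample_id` and `broad_histology`.
#' @param driver_lists Named list from [read_driver_lists()].
#' @param max_partners Promiscuity threshold, exclusive (default 5).
#' @param recurrence_min Minimum sample count within one broad histology for
#'   the recurrence rule, exclusive bound "more than two" (default 2).
#' @return Tibble with one row per retained (sample, fusion), columns
#'   `sample_id`, `fusion_name`, `gene5`, `gene3`, `callers`, `frame`,
#'   `junction_reads`, `spanning_frags`, `retained_by`, `putative_driver`.
#' @export
prioritize_fusions <- function(calls, histology_map, driver_lists,
                               max_partners = 5, recurrence_min = 2) {
  if (nrow(calls) == 0) {
    return(tibble(
      sample_id = character(), fusion_name = character(),
      gene5 = character(), gene3 = character(), callers = character(),
      frame = character(), junction_reads = integer(),
      spanning_frags = integer(), retained_by = character(),
      putative_driver = logical()
    ))
  }
  # promiscuity, counted per sample on distinct partner symbols
  partners5 <- calls |>
    distinct(.data$sample_id, .data$gene5, .data$gene3) |>
    count(.data$sample_id, gene = .data$gene5) |>
    filter(.data$n > max_partners)
  partners3 <- calls |>
    distinct(.data$sample_id, .data$gene5, .data$gene3) |>
    count(.data$sample_id, gene = .data$gene3) |>
    filter(.data$n > max_partners)
  promiscuous <- paste(calls$sample_id, calls$gene5) %in%
    paste(partners5$sample_id, partners5$gene) |
    paste(calls$sample_id, calls$gene3) %in%
      paste(partners3$sample_id, partners3$gene)
  calls <- calls[!promiscuous, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(prioritize_fusions(calls, histology_map, driver_lists))
  }
  per_fusion <- calls |>
    group_by(.data$sample_id, .data$fusion_name) |>
    summarise(
      gene5 = .data$gene5[1], gene3 = .data$gene3[1],
      callers = paste(sort(unique(.data$caller)), collapse = ","),
      n_callers = dplyr::n_distinct(.data$caller),
      frame = .data$frame[1],
      junction_reads = max(.data$junction_reads),
      spanning_frags = max(.data$spanning_frags),
      .groups = "drop"
    ) |>
    left_join(histology_map, by = "sample_id")
  by_hist <- per_fusion |>
    distinct(.data$fusion_name, .data$sample_id, .data$broad_histology) |>
    group_by(.data$fusion_name) |>
    summarise(
      n_histologies = dplyr::n_distinct(.data$broad_histology),
      max_in_histology = max(table(.data$broad_histology)),
      .groups = "drop"
    )
  per_fusion <- per_fusion |>
    left_join(by_hist, by = "fusion_name") |>
    mutate(
      both_callers = .data$n_callers >= 2,
      recurrent = .data$max_in_histology > recurrence_min,
      histology_specific = .data$n_histologies == 1,
      retained = .data$both_callers | .data$recurrent |
        .data$histology_specific
    ) |>
    filter(.data$retained)
  gene_lists <- unlist(driver_lists[c("kinase", "oncogene",
                                      "tumor_suppressor",
                                      "transcription_factor", "cosmic")],
                       use.names = FALSE)
  tcga <- driver_lists$tcga_fusion %||% character(0)
  per_fusion |>
    mutate(
      retained_by = paste0(
        ifelse(.data$both_callers, "both-callers;", ""),
        ifelse(.data$recurrent, "recurrent;", ""),
        ifelse(.data$histology_specific, "histology-specific;", "")
      ),
      putative_driver = .data$gene5 %in% gene_lists |
        .data$gene3 %in% gene_lists |
        .data$fusion_name %in% tcga
    ) |>
    select("sample_id", "fusion_name", "gene5", "gene3", "callers", "frame",
           "junction_reads", "spanning_frags", "retained_by",
           "putative_driver") |>
    arrange(.data$sample_id, .data$fusion_name)
}
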