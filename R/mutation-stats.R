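#' Tumor mutation burden per sample
#'
#' TMB is the number of consensus coding SNVs per megabase of effectively
#' surveyed genome. A base is effectively surveyed when it lies in the
#' intersection of the regions considered by the callers behind the
#' consensus with the coding regions; that intersection supplies both the
#' numerator's mask and the denominator's size.
#'
#' @param snvs Consensus variant-call tibble (1-based `start` positions).
#' @param caller_regions Tibble of intervals surveyed by the callers
#'   (`chromosome`, `start`, `end`; 0-based half-open).
#' @param coding_regions Tibble of coding-sequence intervals (same
#'   convention).
#' @param samples Optional character vector of samples to report (defaults
#'   to the samples present in `snvs`); samples with no qualifying SNV get
#'   TMB 0.
#' @param include_indels Count indels in the numerator as well (default
#'   `FALSE`: SNVs only).
#' @return Tibble with `sample_id`, `n_coding_snvs`, `surveyed_mb`, `tmb`
#'   and the hypermutation `category`.
#' @export
compute_tmb <- function(snvs, caller_regions, coding_regions, samples = NULL,
                        include_indels = FALSE) {
  surveyed <- suppressWarnings(GenomicRanges::intersect(
    GenomicRanges::reduce(segments_to_granges(caller_regions)),
    GenomicRanges::reduce(segments_to_granges(coding_regions))
  ))
  surveyed_mb <- sum(as.numeric(GenomicRanges::width(surveyed))) / 1e6
  if (surveyed_mb <= 0) {
    stop("caller and coding regions do not intersect; TMB undefined",
         call. = FALSE)
  }
  eligible <- snvs
  if (!include_indels) {
    eligible <- eligible[nchar(eligible$reference_allele) == 1 &
                           nchar(eligible$alternate_allele) == 1, ,
                         drop = FALSE]
  }
  if (nrow(eligible) > 0) {
    pos <- GenomicRanges::GRanges(
      eligible$chromosome, IRanges::IRanges(eligible$start, eligible$start)
    )
    inside <- IRanges::overlapsAny(pos, surveyed)
    eligible <- eligible[inside, , drop = FALSE]
  }
  samples <- samples %||% sort(unique(snvs$sample_id))
  tibble(
    sample_id = samples,
    n_coding_snvs = vapply(samples, function(s) {
      sum(eligible$sample_id == s)
    }, integer(1), USE.NAMES = FALSE),
    surveyed_mb = surveyed_mb
  ) |>
    mutate(
      tmb = .data$n_coding_snvs / surveyed_mb,
      category = classify_hypermutation(.data$tmb)
    )
}

#' Classify tumor mutation burden into hypermutation categories
#'
#' Strict thresholds: a TMB above 100 Mut/Mb is ultra-hypermutant, above 10
#' (and at most 100) is hypermutant, and anything else — including exactly
#' 10 — is normal.
#'
#' @param tmb Numeric vector of TMB values (Mut/Mb); must be non-negative.
#' @return Character vector of categories.
#' @export
#' @examples
#' classify_hypermutation(c(5, 35.9, 187.4, 10))
classify_hypermutation <- function(tmb) {
  if (any(is.na(tmb)) || any(tmb < 0)) {
    stop("TMB values must be non-negative and non-missing", call. = FALSE)
  }
  dplyr::case_when(
    tmb > 100 ~ "ultra-hypermutant",
    tmb > 10 ~ "hypermutant",
    TRUE ~ "normal"
  )
}

#' Tally recurrently mutated genes
#'
#' Counts, per gene, the number of distinct samples carrying at least one
#' qualifying nonsynonymous mutation: consequence class High or Moderate and
#' variant allele fraction above 5%. The top `top_n` genes are returned with
#' a deterministic tie-break (count descending, then gene name ascending).
#'
#' @param snvs Consensus variant-call tibble with `consequence_class`,
#'   `t_ref_count`, `t_alt_count`, `hugo_symbol`.
#' @param samples Optional independent sample set to restrict to.
#' @param top_n Number of genes to return (default 50).
#' @param min_vaf VAF threshold, exclusive (default 0.05).
#' @return Tibble with `gene` and `n_samples`, ranked.
#' @export
tally_mutated_genes <- function(snvs, samples = NULL, top_n = 50,
                                min_vaf = 0.05) {
  calls <- snvs
  if (!is.null(samples)) {
    calls <- calls[calls$sample_id %in% samples, , drop = FALSE]
  }
  depth <- calls$t_ref_count + calls$t_alt_count
  vaf <- ifelse(!is.na(depth) & depth > 0, calls$t_alt_count / depth, NA)
  calls <- calls[
    !is.na(calls$consequence_class) &
      tolower(calls$consequence_class) %in% c("high", "moderate") &
      !is.na(vaf) & vaf > min_vaf & !is.na(calls$hugo_symbol),
    , drop = FALSE
  ]
  calls |>
    distinct(.data$hugo_symbol, .data$sample_id) |>
    count(gene = .data$hugo_symbol, name = "n_samples") |>
    arrange(desc(.data$n_samples), .data$gene) |>
    slice_head(n = top_n)
}

#' Gene-by-sample mutation indicator matrix
#'
#' @param snvs Consensus variant-call tibble.
#' @param genes Genes to include as rows (e.g. from
#'   [tally_mutated_genes()]).
#' @param samples Samples to include as columns.
#' @param min_vaf VAF threshold, exclusive (default 0.05).
#' @return Logical matrix, genes by samples.
#' @export
mutation_matrix <- function(snvs, genes, samples, min_vaf = 0.05) {
  depth <- snvs$t_ref_count + snvs$t_alt_count
  vaf <- ifelse(!is.na(depth) & depth > 0, snvs$t_alt_count / depth, NA)
  qual <- snvs[
    !is.na(snvs$consequence_class) &
      tolower(snvs$consequence_class) %in% c("high", "moderate") &
      !is.na(vaf) & vaf > min_vaf,
    , drop = FALSE
  ]
  m <- matrix(FALSE, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  hit <- qual[qual$hugo_symbol %in% genes & qual$sample_id %in% samples, ,
              drop = FALSE]
  if (nrow(hit) > 0) {
    m[cbind(hit$hugo_symbol, hit$sample_id)] <- TRUE
  }
  m
}

#' Pairwise mutation co-occurrence statistics
#'
#' For every unordered gene pair, cross-tabulates mutated/wild-type sample
#' counts, runs a two-sided Fisher exact test, and reports the
#' co-occurrence score I * (-log10 p), where I is +1 when the conditional
#' maximum-likelihood odds ratio exceeds 1 (co-occurrence) and -1 otherwise
#' (mutual exclusivity; an odds ratio of exactly 1 takes the -1 branch by
#' the rule's literal wording, with a near-zero score magnitude in
#' practice). Benjamini-Hochberg q values are computed across all tested
#' pairs.
#'
#' @param mut A logical gene-by-sample matrix (see [mutation_matrix()]).
#' @return Tibble with one row per gene pair: `gene_a`, `gene_b`, the 2x2
#'   counts `n11`, `n10`, `n01`, `n00`, `odds_ratio`, `p_value`, `q_value`
#'   and `score`.
#' @export
cooccurrence <- function(mut) {
  if (!is.matrix(mut) || !is.logical(mut)) {
    stop("mut must be a logical gene-by-sample matrix", call. = FALSE)
  }
  genes <- rownames(mut)
  if (length(genes) < 2) {
    stop("need at least two genes", call. = FALSE)
  }
  pairs <- utils::combn(seq_along(genes), 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    a <- mut[i, ]
    b <- mut[j, ]
    n11 <- sum(a & b)
    n10 <- sum(a & !b)
    n01 <- sum(!a & b)
    n00 <- sum(!a & !b)
    ft <- stats::fisher.test(matrix(c(n11, n01, n10, n00), nrow = 2))
    or <- unname(ft$estimate)
    score_sign <- if (!is.na(or) && or > 1) 1 else -1
    tibble(
      gene_a = genes[i], gene_b = genes[j],
      n11 = n11, n10 = n10, n01 = n01, n00 = n00,
      odds_ratio = or, p_value = ft$p.value,
      score = score_sign * (-log10(ft$p.value))
    )
  })
  out <- bind_rows(res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out |>
    select("gene_a", "gene_b", "n11", "n10", "n01", "n00", "odds_ratio",
           "p_value", "q_value", "score")
}
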