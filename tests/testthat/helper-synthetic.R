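# Shared fixtures: all built in code, no stored data.

zero_noise <- list(fp_rate = 0, contaminants = 0, fusion_artifacts = FALSE,
                   boundary_jitter = 0, mnv_rate = 0)

# minimal variant-call record with sane defaults
make_call <- function(sample_id = "S1", chromosome = "chr1", start = 100L,
                      ref = "A", alt = "G", caller = "strelka2",
                      t_ref_count = 60, t_alt_count = 40, n_depth = 40,
                      population_af = 0, consequence_class = "Moderate",
                      hugo_symbol = "GENE1", protein_position = NA_integer_,
                      hgvsp_short = NA_character_, hotspot = FALSE,
                      tert_promoter = "none") {
  tibble::tibble(
    sample_id = sample_id, chromosome = chromosome,
    start = as.integer(start), reference_allele = ref,
    alternate_allele = alt, caller = caller,
    t_ref_count = t_ref_count, t_alt_count = t_alt_count,
    n_depth = n_depth, population_af = population_af,
    consequence_class = consequence_class, hugo_symbol = hugo_symbol,
    protein_position = protein_position, hgvsp_short = hgvsp_short,
    hotspot = hotspot, tert_promoter = tert_promoter
  )
}

make_segment <- function(sample_id = "S1", chromosome = "chr1",
                         start = 0L, end = 10000L, copy_number = 3L,
                         status = "gain", log2_ratio = NA_real_,
                         p_value = NA_real_, ploidy = 2L,
                         caller = "cnvkit", filter = NA_character_) {
  tibble::tibble(
    sample_id = sample_id, chromosome = chromosome,
    start = as.integer(start), end = as.integer(end),
    copy_number = copy_number, status = status,
    log2_ratio = log2_ratio, p_value = p_value,
    ploidy = ploidy, caller = caller, filter = filter
  )
}

# random variant tables sharing a configurable overlap, for oracle checks
random_call_table <- function(n, seed, n_samples = 4, span = 400L) {
  withr::with_seed(seed, {
    tibble::tibble(
      sample_id = paste0("S", sample.int(n_samples, n, replace = TRUE)),
      chromosome = paste0("chr", sample.int(3, n, replace = TRUE)),
      start = sample.int(span, n, replace = TRUE),
      reference_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alternate_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      caller = NA_character_,
      t_ref_count = 60, t_alt_count = 40, n_depth = 40, population_af = 0,
      consequence_class = "Moderate", hugo_symbol = "GENE1",
      protein_position = NA_integer_, hgvsp_short = NA_character_,
      hotspot = FALSE, tert_promoter = "none"
    ) |>
      dplyr::filter(reference_allele != alternate_allele)
  })
}

random_segment_table <- function(n, seed, n_samples = 2) {
  withr::with_seed(seed, {
    start <- sample.int(500000L, n, replace = TRUE)
    tibble::tibble(
      sample_id = paste0("S", sample.int(n_samples, n, replace = TRUE)),
      chromosome = paste0("chr", sample.int(2, n, replace = TRUE)),
      start = start,
      end = start + sample.int(80000L, n, replace = TRUE) + 1000L,
      copy_number = sample(c(0L, 1L, 3L, 4L, 6L), n, replace = TRUE),
      log2_ratio = NA_real_, p_value = NA_real_, ploidy = 2L,
      caller = sample(c("controlfreec", "cnvkit", "manta"), n,
                      replace = TRUE)
    ) |>
      dplyr::mutate(status = ifelse(copy_number > ploidy, "gain",
                                    ifelse(copy_number < ploidy, "loss",
                                           "neutral")))
  })
}

# two-sided Fisher p by exhaustive hypergeometric tail enumeration,
# independent of fisher.test: sum P(k) over all k with P(k) <= P(a),
# using the same relative tolerance convention as the exact test
oracle_fisher_p <- function(n11, n10, n01, n00) {
  r <- n11 + n10
  c1 <- n11 + n01
  n <- n11 + n10 + n01 + n00
  lo <- max(0L, r + c1 - n)
  hi <- min(r, c1)
  k <- lo:hi
  probs <- stats::dhyper(k, c1, n - c1, r)
  p_obs <- probs[match(n11, k)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# evidence builder shorthand for engine tests
ev <- function(..., sample_id = "S1") {
  pedcns::subtype_evidence(sample_id = sample_id, ...)
}

snv_ev <- function(gene, change = NA_character_,
                   position = NA_integer_, hotspot = FALSE,
                   domain = NA_character_) {
  tibble::tibble(gene = gene, protein_change = change,
                 protein_position = as.integer(position),
                 hotspot = hotspot, domain = domain)
}

fusion_ev <- function(name) {
  parts <- stringr::str_split_fixed(name, "--", 2)
  tibble::tibble(fusion_name = name, gene5 = parts[, 1],
                 gene3 = parts[, 2])
}
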