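# Simulators turning the truth set into per-caller output tables. Noise
# processes are simple Bernoulli/uniform draws: the downstream filters are
# rule-based, so the generator only needs to satisfy or violate each rule.

# truth SNV rows -> internal variant-call records with read support
snv_base_records <- function(snv, caller) {
  tibble(
    sample_id = snv$sample_id,
    chromosome = snv$chromosome,
    start = as.integer(snv$start),
    reference_allele = snv$reference_allele,
    alternate_allele = snv$alternate_allele,
    caller = caller,
    t_ref_count = as.integer(round(100 * (1 - snv$vaf))),
    t_alt_count = as.integer(round(100 * snv$vaf)),
    n_depth = 40,
    population_af = 0,
    consequence_class = snv$consequence_class,
    hugo_symbol = snv$gene,
    protein_position = snv$protein_position,
    hgvsp_short = snv$protein_change,
    hotspot = FALSE,
    tert_promoter = "none"
  )
}

# collapse adjacent mnv_group members into one MNV record (callers that
# report multi-nucleotide variants as a single row)
as_mnv_records <- function(calls, groups) {
  grouped <- !is.na(groups)
  if (!any(grouped)) {
    return(calls)
  }
  singles <- calls[!grouped, , drop = FALSE]
  merged <- lapply(split(which(grouped), groups[grouped]), function(idx) {
    rows <- calls[idx, , drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    out <- rows[1, , drop = FALSE]
    out$reference_allele <- paste(rows$reference_allele, collapse = "")
    out$alternate_allele <- paste(rows$alternate_allele, collapse = "")
    out
  })
  bind_rows(singles, bind_rows(merged))
}

#' Simulate three SNV callers' output tables
#'
#' Every true variant appears in all three caller tables. Adjacent true
#' SNV pairs (shared `mnv_group`) are emitted as one multi-nucleotide
#' record by two of the callers and as split SNVs by the third, since one
#' caller does not report MNVs. Caller-specific false positives are
#' injected at the configured rate, and a configured number of
#' germline-like contaminants — carrying a high population allele
#' frequency or a low matched-normal depth — are shared by all three
#' callers, so only the germline-like filter can remove them.
#'
#' @param truth Truth set from [generate_cohort()].
#' @param config The [cohort_config()].
#' @return List of variant-call tibbles `strelka2`, `mutect2`, `lancet`.
#' @export
simulate_multicaller_snv <- function(truth, config) {
  snv <- truth$snv
  with_seed(derive_seed(config$seed, 10L), {
    strelka <- snv_base_records(snv, "strelka2")
    mutect <- as_mnv_records(snv_base_records(snv, "mutect2"),
                             snv$mnv_group)
    lancet <- as_mnv_records(snv_base_records(snv, "lancet"),
                             snv$mnv_group)
    samples <- unique(snv$sample_id)
    add_noise <- function(calls, caller) {
      n_fp <- if (length(samples) == 0) 0 else
        stats::rbinom(1, max(nrow(snv), 1), config$noise$fp_rate)
      if (n_fp > 0) {
        genes <- sample(SYNTHETIC_GENE_REGISTRY, n_fp, replace = TRUE)
        loc <- gene_locus(genes)
        fp <- tibble(
          sample_id = sample(samples, n_fp, replace = TRUE),
          chromosome = loc$chromosome,
          start = loc$start + sample(5000:9999, n_fp, replace = TRUE),
          reference_allele = "G", alternate_allele = "A",
          caller = caller, t_ref_count = 90L, t_alt_count = 10L,
          n_depth = 40, population_af = 0,
          consequence_class = "Low", hugo_symbol = genes,
          protein_position = NA_integer_, hgvsp_short = NA_character_,
          hotspot = FALSE, tert_promoter = "none"
        )
        calls <- bind_rows(calls, fp)
      }
      calls
    }
    strelka <- add_noise(strelka, "strelka2")
    mutect <- add_noise(mutect, "mutect2")
    lancet <- add_noise(lancet, "lancet")
    n_cont <- config$noise$contaminants
    if (n_cont > 0 && length(samples) > 0) {
      genes <- sample(c("PTEN", "NF2", "ATRX"), n_cont, replace = TRUE)
      loc <- gene_locus(genes)
      high_af <- seq_len(n_cont) %% 2 == 1
      cont <- tibble(
        sample_id = sample(samples, n_cont, replace = TRUE),
        chromosome = loc$chromosome,
        start = loc$start + 4000L + seq_len(n_cont),
        reference_allele = "T", alternate_allele = "C",
        caller = NA_character_,
        t_ref_count = 50L, t_alt_count = 50L,
        n_depth = ifelse(high_af, 40, 5),
        population_af = ifelse(high_af, 0.01, 0),
        consequence_class = "Moderate", hugo_symbol = genes,
        protein_position = NA_integer_, hgvsp_short = NA_character_,
        hotspot = FALSE, tert_promoter = "none"
      )
      strelka <- bind_rows(strelka, mutate(cont, caller = "strelka2"))
      mutect <- bind_rows(mutect, mutate(cont, caller = "mutect2"))
      lancet <- bind_rows(lancet, mutate(cont, caller = "lancet"))
    }
    list(strelka2 = strelka, mutect2 = mutect, lancet = lancet)
  })
}

#' Simulate three CNV callers and a structural-variant table
#'
#' True segments appear in all three callers with boundaries jittered by
#' at most the configured number of bp; Control-FREEC also reports a
#' significance p value, and Manta segments carry a PASS filter. Per
#' caller, single-caller false-positive segments are injected at the
#' configured rate. When `noise$noisy_sample` names a sample, its
#' Control-FREEC table receives more than 2,500 segments so the
#' per-sample caller file is dropped downstream. Breakpoints of true
#' segments are emitted as PASS structural-variant calls (plus a few
#' non-PASS decoys).
#'
#' @inheritParams simulate_multicaller_snv
#' @return List of tibbles `freec`, `cnvkit`, `manta` (segments) and `sv`
#'   (breakpoints).
#' @export
simulate_multicaller_cnv <- function(truth, config) {
  cnv <- truth$cnv
  genome <- config$genome$chromosomes
  with_seed(derive_seed(config$seed, 20L), {
    jitter <- config$noise$boundary_jitter
    emit <- function(caller) {
      if (nrow(cnv) == 0) {
        out <- cnv
        out$log2_ratio <- double(0)
        out$p_value <- double(0)
        out$caller <- character(0)
        out$filter <- character(0)
        return(out)
      }
      out <- cnv
      if (jitter > 0) {
        len <- genome$length[match(out$chromosome, genome$chromosome)]
        out$start <- pmax(0L, out$start +
                            sample(-jitter:jitter, nrow(out),
                                   replace = TRUE))
        out$end <- pmin(as.integer(len),
                        out$end + sample(-jitter:jitter, nrow(out),
                                         replace = TRUE))
        out$start <- pmin(out$start, out$end - 1L)
      }
      out$log2_ratio <- log2(pmax(out$copy_number, 0.5) / out$ploidy)
      out$p_value <- if (caller == "controlfreec") 0.001 else NA_real_
      out$caller <- caller
      out$filter <- if (caller == "manta") "PASS" else NA_character_
      out
    }
    freec <- emit("controlfreec")
    cnvkit <- emit("cnvkit")
    manta <- emit("manta")
    samples <- unique(cnv$sample_id)
    add_fp <- function(seg, caller) {
      n_fp <- if (length(samples) == 0) 0 else
        stats::rbinom(1, max(nrow(cnv), 1), config$noise$fp_rate)
      if (n_fp == 0) {
        return(seg)
      }
      chrom <- sample(genome$chromosome, n_fp, replace = TRUE)
      len <- genome$length[match(chrom, genome$chromosome)]
      start <- vapply(len, function(l) {
        as.integer(stats::runif(1, 100000, l - 200000))
      }, integer(1))
      fp_p <- if (caller == "controlfreec") 0.001 else NA_real_
      fp_filter <- if (caller == "manta") "PASS" else NA_character_
      fp <- tibble(
        sample_id = sample(samples, n_fp, replace = TRUE),
        chromosome = chrom, start = start, end = start + 100000L,
        copy_number = 3L, status = "gain", ploidy = 2L,
        log2_ratio = log2(3 / 2),
        p_value = fp_p,
        caller = caller,
        filter = fp_filter
      )
      bind_rows(seg, fp)
    }
    freec <- add_fp(freec, "controlfreec")
    cnvkit <- add_fp(cnvkit, "cnvkit")
    manta <- add_fp(manta, "manta")
    noisy <- config$noise$noisy_sample
    if (!is.null(noisy)) {
      starts <- as.integer(seq(100000, by = 1000, length.out = 2501))
      freec <- bind_rows(freec, tibble(
        sample_id = noisy, chromosome = "chr2", start = starts,
        end = starts + 500L, copy_number = 3L, status = "gain",
        ploidy = 2L, log2_ratio = log2(3 / 2), p_value = 0.001,
        caller = "controlfreec", filter = NA_character_
      ))
    }
    sv <- if (nrow(cnv) == 0) {
      tibble(sample_id = character(), chromosome = character(),
             position = integer(), sv_type = character(),
             filter = character())
    } else {
      bind_rows(
        tibble(sample_id = cnv$sample_id, chromosome = cnv$chromosome,
               position = cnv$start, sv_type = "BND", filter = "PASS"),
        tibble(sample_id = cnv$sample_id, chromosome = cnv$chromosome,
               position = cnv$end, sv_type = "BND", filter = "PASS"),
        tibble(sample_id = cnv$sample_id[1], chromosome = "chr2",
               position = 123456L, sv_type = "BND", filter = "LowQual")
      )
    }
    list(freec = freec, cnvkit = cnvkit, manta = manta, sv = sv)
  })
}

FUSION_ARTIFACT_GENES <- c("ARTJ1", "ARTJ2", "ARTS1", "ARTS2", "ARTU1",
                           "ARTU2", "ARTP", paste0("ARTQ", 1:6),
                           "ARTL1", "ARTL2")

#' Simulate fusion caller tables and expression matrices
#'
#' True fusions appear in both caller dialects with at least one junction
#' read, in-frame, and with both partners expressed (TPM > 1). When
#' artifact planting is enabled, one artifact fusion per filter class is
#' added, each violating exactly one rule: zero junction reads; spanning
#' minus junction reads above ten; both partners unexpressed; a
#' promiscuous 5' partner fused to six genes in one sample; and a
#' single-caller call planted once in each of two broad histologies (so
#' it is neither recurrent nor histology-specific). The FPKM matrix
#' contains a gene symbol mapped to two identifiers (exercising the
#' collapse step), an all-zero row, and the planted marker-gene
#' overexpression driving the expression-based subtyping rules.
#'
#' @inheritParams simulate_multicaller_snv
#' @param histology The histology table from [generate_cohort()] (used to
#'   pick artifact host samples and the RNA sample set).
#' @return List with `starfusion` and `arriba` caller tables and `fpkm`
#'   and `tpm` expression tibbles.
#' @export
simulate_fusions_and_expression <- function(truth, config, histology) {
  rna_samples <- histology$sample_id[histology$sample_type == "tumor" &
                                       histology$has_rna]
  with_seed(derive_seed(config$seed, 30L), {
    fus <- truth$fusion
    n <- nrow(fus)
    junction <- if (n > 0) sample(5:20, n, replace = TRUE) else integer(0)
    spanning <- junction + if (n > 0) {
      sample(0:5, n, replace = TRUE)
    } else {
      integer(0)
    }
    star <- tibble(
      sample_id = fus$sample_id, FusionName = fus$fusion_name,
      JunctionReadCount = junction, SpanningFragCount = spanning,
      PROT_FUSION_TYPE = "INFRAME"
    )
    arriba <- tibble(
      sample_id = fus$sample_id, gene1 = fus$gene5, gene2 = fus$gene3,
      split_reads1 = pmax(junction - 2L, 1L), split_reads2 = 2L,
      discordant_mates = spanning, reading_frame = "in-frame",
      confidence = "high"
    )
    art_star <- star[0, ]
    art_arriba <- arriba[0, ]
    if (isTRUE(config$noise$fusion_artifacts) && length(rna_samples) > 0) {
      hist_tumor <- histology[histology$sample_type == "tumor" &
                                histology$has_rna, , drop = FALSE]
      host <- rna_samples[1]
      both <- function(sample, name, junction, spanning,
                       frame = "INFRAME") {
        parts <- stringr::str_split_fixed(name, "--", 2)
        art_star <<- bind_rows(art_star, tibble(
          sample_id = sample, FusionName = name,
          JunctionReadCount = junction, SpanningFragCount = spanning,
          PROT_FUSION_TYPE = frame
        ))
        art_arriba <<- bind_rows(art_arriba, tibble(
          sample_id = sample, gene1 = parts[, 1], gene2 = parts[, 2],
          split_reads1 = junction, split_reads2 = 0L,
          discordant_mates = spanning, reading_frame = "in-frame",
          confidence = "high"
        ))
      }
      both(host, "ARTJ1--ARTJ2", 0L, 3L)
      both(host, "ARTS1--ARTS2", 2L, 13L)
      both(host, "ARTU1--ARTU2", 4L, 5L)
      art_star <- bind_rows(art_star, tibble(
        sample_id = host, FusionName = paste0("ARTP--ARTQ", 1:6),
        JunctionReadCount = 5L, SpanningFragCount = 6L,
        PROT_FUSION_TYPE = "INFRAME"
      ))
      two_hist <- hist_tumor |>
        distinct(.data$broad_histology, .keep_all = TRUE) |>
        slice_head(n = 2)
      if (nrow(two_hist) == 2) {
        art_star <- bind_rows(art_star, tibble(
          sample_id = two_hist$sample_id, FusionName = "ARTL1--ARTL2",
          JunctionReadCount = 4L, SpanningFragCount = 5L,
          PROT_FUSION_TYPE = "INFRAME"
        ))
      }
    }
    starfusion <- bind_rows(star, art_star)
    arriba_all <- bind_rows(arriba, art_arriba)
    # expression panel: subtype markers, fusion partners, housekeeping,
    # a multi-mapped symbol and an all-zero gene
    markers <- c("LIN28A", "FOXR2", "CXorf67", "TKTL1", "GPBP17", "IFT46",
                 "RELA", "L1CAM", "ARL4D", "CLDN1")
    partner_genes <- unique(c(fus$gene5, fus$gene3,
                              FUSION_ARTIFACT_GENES))
    panel <- unique(c(markers, partner_genes, paste0("HK", 1:5)))
    n_rna <- length(rna_samples)
    base_val <- function(gene) {
      if (gene %in% c("ARTU1", "ARTU2")) {
        return(rep(0, n_rna))
      }
      if (gene %in% partner_genes) {
        return(stats::runif(n_rna, 7.5, 8.5))
      }
      stats::runif(n_rna, 4.5, 5.5)
    }
    mat <- vapply(panel, base_val, numeric(n_rna))
    mat <- matrix(mat, nrow = n_rna,
                  dimnames = list(rna_samples, panel))
    for (i in seq_len(nrow(truth$overexpression))) {
      s <- truth$overexpression$sample_id[i]
      g <- truth$overexpression$gene[i]
      if (s %in% rna_samples && g %in% panel) {
        mat[s, g] <- 100
      }
    }
    expr <- tibble(
      gene_id = sprintf("ENSG%05d", seq_along(panel)),
      gene_symbol = panel
    )
    expr <- bind_cols(expr, as_tibble(t(mat)))
    dup_hi <- tibble(gene_id = "ENSG90001", gene_symbol = "DUPGENE")
    dup_hi <- bind_cols(dup_hi, as_tibble(
      t(matrix(stats::runif(n_rna, 9.5, 10.5), nrow = n_rna,
               dimnames = list(rna_samples, "DUPGENE")))
    ))
    dup_lo <- tibble(gene_id = "ENSG90002", gene_symbol = "DUPGENE")
    dup_lo <- bind_cols(dup_lo, as_tibble(
      t(matrix(stats::runif(n_rna, 0.5, 1.5), nrow = n_rna,
               dimnames = list(rna_samples, "DUPGENE")))
    ))
    dead <- tibble(gene_id = "ENSG90003", gene_symbol = "DEADGENE")
    dead <- bind_cols(dead, as_tibble(
      t(matrix(0, nrow = n_rna, dimnames = list(rna_samples, "DEADGENE")))
    ))
    fpkm <- bind_rows(expr, dup_hi, dup_lo, dead)
    list(starfusion = starfusion, arriba = arriba_all, fpkm = fpkm,
         tpm = fpkm)
  })
}

#' Simulate sex-chromosome read statistics per patient
#'
#' Females receive Y-read fractions well below 0.2 and males well above
#' 0.4 (after chromosome-length normalization), so the threshold rule
#' recovers the planted genetic sex exactly.
#'
#' @inheritParams simulate_multicaller_snv
#' @return Tibble usable by [estimate_germline_sex()], one row per
#'   patient's normal specimen.
#' @export
simulate_sex_read_stats <- function(truth, config) {
  sex <- truth$sex
  genome <- config$genome$chromosomes
  x_len <- genome$length[genome$chromosome == "chrX"]
  y_len <- genome$length[genome$chromosome == "chrY"]
  with_seed(derive_seed(config$seed, 40L), {
    n <- nrow(sex)
    f_target <- ifelse(sex$genetic_sex == "Female",
                       stats::runif(n, 0.01, 0.1),
                       stats::runif(n, 0.45, 0.55))
    x_reads <- as.integer(round(stats::runif(n, 0.9, 1.1) * 1e6))
    # solve y reads so the normalized fraction equals the target
    norm_x <- x_reads / x_len
    y_reads <- as.integer(round(f_target / (1 - f_target) * norm_x * y_len))
    tibble(
      sample_id = paste0("BS_", sprintf("%03d", seq_len(n)), "-N"),
      patient_id = sex$patient_id,
      x_mapped_reads = x_reads, y_mapped_reads = y_reads,
      x_length = x_len, y_length = y_len,
      reported_gender = sex$genetic_sex
    )
  })
}
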