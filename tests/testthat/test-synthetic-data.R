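test_that("configuration validates probability vectors and sizes", {
  expect_error(cohort_config(cancer_group_weights = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(cohort_config(tumor_event_mix = c(primary = -1,
                                                 progressive = 2)),
               "sum to 1")
  expect_error(cohort_config(n_patients = -1), "non-negative")
  bad_genome <- toy_genome()
  bad_genome$chromosomes$length[1] <- 0L
  expect_error(cohort_config(genome = bad_genome), "strictly positive")
})

test_that("the generator is deterministic and honors n_patients = 0", {
  cfg <- cohort_config(mode = "random", n_patients = 12, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_identical(simulate_multicaller_snv(a$truth, cfg),
                   simulate_multicaller_snv(b$truth, cfg))
  expect_identical(simulate_multicaller_cnv(a$truth, cfg),
                   simulate_multicaller_cnv(b$truth, cfg))
  # a different seed changes the cohort
  c <- generate_cohort(cohort_config(mode = "random", n_patients = 12,
                                     seed = 100))
  expect_false(identical(a$histology, c$histology))
  empty <- generate_cohort(cohort_config(mode = "random", n_patients = 0))
  expect_equal(nrow(empty$histology), 0)
  expect_equal(nrow(empty$truth$snv), 0)
  expect_equal(nrow(empty$truth$subtype), 0)
})

test_that("every truth record references a generated sample and patients have tumor+normal", {
  cfg <- cohort_config(mode = "rule-coverage", seed = 4)
  cohort <- generate_cohort(cfg)
  hist <- cohort$histology
  samples <- hist$sample_id
  for (tbl in cohort$truth[c("snv", "cnv", "fusion", "overexpression",
                             "subtype", "mb_scores")]) {
    expect_true(all(tbl$sample_id %in% samples))
  }
  expect_true(all(cohort$truth$sex$patient_id %in% hist$patient_id))
  per_patient <- split(hist$sample_type, hist$patient_id)
  expect_true(all(vapply(per_patient, function(x) {
    sum(x == "normal") == 1 && sum(x == "tumor") >= 1
  }, logical(1))))
})

test_that("rule-coverage mode plants every engine branch at least once", {
  cohort <- generate_cohort(cohort_config(mode = "rule-coverage"))
  labels <- cohort$truth$subtype$molecular_subtype
  required <- c(
    "DMG, H3 K28", "DMG, H3 K28, BRAF V600E", "HGG, H3 G35", "HGG, IDH",
    "HGG, BRAF V600E", "HGG, H3 wild type", "DMG, H3 K28, TP53 activated",
    "DMG, H3 K28, TP53 loss",
    "LGG, KIAA1549-BRAF", "LGG, BRAF V600E, CDKN2A/B", "LGG, NF1-somatic",
    "LGG, NF1-germline", "LGG, IDH", "LGG, H3", "LGG, other MAPK",
    "LGG, RTK", "LGG, FGFR", "LGG, MYB/MYBL1", "LGG, wild type",
    "LGG, To be classified", "SEGA, wild type", "GNT, KIAA1549-BRAF",
    "ETMR, C19MC altered", "ETMR, NOS", "CNS HGNET-MN1",
    "CNS HGNET-BCOR", "CNS NB-FOXR2", "CNS EFT-CIC", "CNS embryonal, NOS",
    "EPN, ST RELA", "EPN, ST YAP1", "EPN, PF A", "EPN, PF B",
    "EPN, To be classified",
    "CRANIO, PAP", "CRANIO, ADAM", "CRANIO, To be classified",
    "CNC", "EVN", "EWS",
    "MB, SHH", "MB, WNT", "MB, group 3", "MB, group 4",
    "MB, To be classified"
  )
  expect_true(all(required %in% labels))
})

test_that("MNV pairs are emitted as one record by two callers and split by the third", {
  cfg <- cohort_config(mode = "random", n_patients = 6, seed = 13,
                       noise = list(mnv_rate = 1, fp_rate = 0,
                                    contaminants = 0))
  cohort <- generate_cohort(cfg)
  tables <- simulate_multicaller_snv(cohort$truth, cfg)
  multi <- nchar(tables$mutect2$reference_allele) > 1
  expect_true(any(multi))
  expect_true(all(nchar(tables$strelka2$reference_allele) == 1))
  one_mnv <- tables$mutect2[multi, ][1, ]
  expect_equal(nchar(one_mnv$reference_allele), 2)
  # after decomposition the three caller sets are identical
  key <- function(df) {
    sort(paste(df$sample_id, df$chromosome, df$start,
               df$reference_allele, df$alternate_allele))
  }
  expect_equal(key(decompose_mnv(tables$mutect2)), key(tables$strelka2))
  expect_equal(key(decompose_mnv(tables$lancet)), key(tables$strelka2))
})

test_that("with zero noise the caller tables agree and consensus recovers SNV truth", {
  cfg <- cohort_config(mode = "random", n_patients = 8, seed = 21,
                       noise = zero_noise)
  res <- run_synthetic_pipeline(cfg)
  key <- function(df) {
    sort(paste(df$sample_id, df$chromosome, df$start,
               df$reference_allele, df$alternate_allele))
  }
  expect_equal(key(res$consensus_snv), key(res$truth$snv))
})

test_that("injected germline-like contaminants are removed by the depth/AF filter", {
  cfg <- cohort_config(mode = "random", n_patients = 8, seed = 22,
                       noise = list(fp_rate = 0, contaminants = 4,
                                    mnv_rate = 0,
                                    fusion_artifacts = FALSE))
  res <- run_synthetic_pipeline(cfg)
  key <- function(df) {
    sort(paste(df$sample_id, df$chromosome, df$start,
               df$reference_allele, df$alternate_allele))
  }
  # contaminants are shared by all three callers, so only the
  # germline-like filter can be responsible for their absence
  expect_equal(key(res$consensus_snv), key(res$truth$snv))
  raw_shared <- intersect_callers(res$snv_tables$strelka2,
                                  res$snv_tables$mutect2,
                                  res$snv_tables$lancet)
  expect_gt(nrow(raw_shared), nrow(res$truth$snv))
})

test_that("zero-jitter zero-noise consensus equals the true CNV segments", {
  cfg <- cohort_config(mode = "rule-coverage", seed = 23,
                       noise = zero_noise)
  res <- run_synthetic_pipeline(cfg)
  key <- function(df) {
    sort(paste(df$sample_id, df$chromosome, df$start, df$end,
               df$copy_number))
  }
  expect_equal(key(res$consensus_cnv), key(res$truth$cnv))
})

test_that("a noisy Control-FREEC file is dropped without losing consensus support", {
  base <- cohort_config(mode = "rule-coverage", seed = 24,
                        noise = zero_noise)
  cohort <- generate_cohort(base)
  noisy_sample <- cohort$truth$cnv$sample_id[1]
  cfg <- cohort_config(mode = "rule-coverage", seed = 24,
                       noise = utils::modifyList(
                         zero_noise, list(noisy_sample = noisy_sample)
                       ))
  tables <- simulate_multicaller_cnv(cohort$truth, cfg)
  expect_gt(sum(tables$freec$sample_id == noisy_sample), 2500)
  filtered <- filter_caller_segments(tables$freec, tables$cnvkit,
                                     tables$manta)
  expect_equal(sum(filtered$freec$sample_id == noisy_sample), 0)
  # the other two callers still reach consensus for that sample
  cons <- merge_and_filter(consensus_intervals(filtered),
                           base$genome$exclusions)
  truth_s <- cohort$truth$cnv[cohort$truth$cnv$sample_id == noisy_sample, ]
  got_s <- cons[cons$sample_id == noisy_sample, ]
  expect_equal(sort(paste(got_s$start, got_s$end)),
               sort(paste(truth_s$start, truth_s$end)))
})

test_that("planted marker-gene z-scores exceed 3 in the generated matrix", {
  cfg <- cohort_config(mode = "rule-coverage", seed = 25)
  res <- run_synthetic_pipeline(cfg)
  over <- res$truth$overexpression
  for (i in seq_len(nrow(over))) {
    expect_gt(res$expression_z[over$gene[i], over$sample_id[i]], 3)
  }
  # the multi-mapped symbol collapsed to its higher-expressed identifier
  dup <- res$collapsed_fpkm[res$collapsed_fpkm$gene_symbol == "DUPGENE", ]
  expect_equal(dup$gene_id, "ENSG90001")
})

test_that("the rule-coverage cohort is labeled in full agreement with planted subtypes", {
  res <- run_synthetic_pipeline(cohort_config(mode = "rule-coverage",
                                              seed = 26))
  got <- res$integrated_histology
  cmp <- dplyr::left_join(res$truth$subtype,
                          got[, c("sample_id", "molecular_subtype")],
                          by = "sample_id",
                          suffix = c("_truth", "_called"))
  expect_equal(cmp$molecular_subtype_called, cmp$molecular_subtype_truth)
  # emitted label set equals the planted label set
  expect_setequal(
    got$molecular_subtype[!is.na(got$molecular_subtype)],
    res$truth$subtype$molecular_subtype
  )
})
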