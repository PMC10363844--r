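#' Configuration for the synthetic cohort generator
#'
#' Bundles everything the generator needs: cohort size and composition,
#' the miniature genome model, per-caller noise settings and the master
#' seed. In `"rule-coverage"` mode the cohort is a fixed roster of planted
#' samples covering every subtyping rule branch (and `n_patients` is
#' ignored); in `"random"` mode patients are drawn from
#' `cancer_group_weights`.
#'
#' @param n_patients Number of patients (random mode).
#' @param mode `"rule-coverage"` or `"random"`.
#' @param cancer_group_weights Named probability vector over cancer groups
#'   (random mode); must sum to 1.
#' @param tumor_event_mix Named probability vector over tumor descriptors
#'   (`primary`, `progressive`); must sum to 1.
#' @param seed Master seed; every simulator derives its stream from it.
#' @param genome Genome model, as from [toy_genome()].
#' @param noise List of noise settings: `fp_rate` (per-caller
#'   false-positive call rate), `boundary_jitter` (CNV boundary jitter in
#'   bp), `mnv_rate` (fraction of SNVs emitted as adjacent 2-base MNV
#'   pairs), `contaminants` (number of germline-like contaminant calls
#'   shared by all callers), `fusion_artifacts` (plant one artifact fusion
#'   per filter class), `noisy_sample` (sample whose Control-FREEC file
#'   gets >2,500 segments, or `NULL`).
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_patients = 20,
                          mode = c("rule-coverage", "random"),
                          cancer_group_weights = c(
                            "Low-grade glioma" = 0.4,
                            "High-grade glioma" = 0.3,
                            "Ependymoma" = 0.15,
                            "Medulloblastoma" = 0.15
                          ),
                          tumor_event_mix = c(primary = 0.8,
                                              progressive = 0.2),
                          seed = 2023L,
                          genome = toy_genome(),
                          noise = list()) {
  mode <- match.arg(mode)
  if (n_patients < 0) {
    stop("n_patients must be non-negative", call. = FALSE)
  }
  for (p in list(cancer_group_weights, tumor_event_mix)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("probability vector must be non-negative and sum to 1",
           call. = FALSE)
    }
  }
  if (any(genome$chromosomes$length <= 0)) {
    stop("all chromosome lengths must be strictly positive", call. = FALSE)
  }
  defaults <- list(fp_rate = 0.1, boundary_jitter = 0, mnv_rate = 0.1,
                   contaminants = 2, fusion_artifacts = TRUE,
                   noisy_sample = NULL)
  noise <- utils::modifyList(defaults, noise)
  structure(list(
    n_patients = as.integer(n_patients), mode = mode,
    cancer_group_weights = cancer_group_weights,
    tumor_event_mix = tumor_event_mix, seed = as.integer(seed),
    genome = genome, noise = noise
  ), class = "cohort_config")
}

derive_seed <- function(seed, stream) {
  (as.integer(seed) * 97L + stream * 7919L) %% 2000000011L
}

# One planted sample covering one subtyping rule branch. `cnv` rows are
# (kind, target, copy_number): kind "arm" targets a whole toy-genome arm
# (e.g. "6q"), kind "gene" a +/-20 kb window around a gene model.
planted <- function(tag, dx, label, free_text = NA, site = NA, age = 8,
                    predisposition = "", snvs = NULL, fusions = NULL,
                    cnv = NULL, overexpress = character(0),
                    mb1 = NA, mb2 = NA, bcor_itd = FALSE, has_rna = TRUE) {
  list(tag = tag, dx = dx, label = label, free_text = free_text,
       site = site, age = age, predisposition = predisposition,
       snvs = snvs, fusions = fusions, cnv = cnv,
       overexpress = overexpress, mb1 = mb1, mb2 = mb2,
       bcor_itd = bcor_itd, has_rna = has_rna)
}

snv_spec <- function(gene, change, position,
                     consequence = "Moderate", vaf = 0.4) {
  tibble(gene = gene, protein_change = change,
         protein_position = as.integer(position),
         consequence_class = consequence, vaf = vaf)
}

cnv_spec <- function(kind, target, copy_number) {
  tibble(kind = kind, target = target, copy_number = as.integer(copy_number))
}

# The rule-coverage roster: every branch of every subtyping engine gets at
# least one sample whose evidence, run through the full pipeline, must
# reproduce the planted label.
rule_coverage_roster <- function() {
  lgg_dx <- "Low-grade glioma/astrocytoma (WHO grade I/II)"
  pnet_dx <- "Supratentorial or Spinal Cord PNET"
  list(
    planted("HGG-01", "High-grade glioma", "DMG, H3 K28",
            snvs = snv_spec("H3F3A", "p.K28M", 28)),
    planted("HGG-02", "High-grade glioma", "DMG, H3 K28, BRAF V600E",
            snvs = bind_rows(snv_spec("HIST1H3B", "p.K28M", 28),
                             snv_spec("BRAF", "p.V600E", 600))),
    planted("HGG-03", "High-grade glioma", "HGG, H3 G35",
            snvs = snv_spec("H3F3A", "p.G35R", 35)),
    planted("HGG-04", "High-grade glioma", "HGG, IDH",
            snvs = snv_spec("IDH1", "p.R132H", 132)),
    planted("HGG-05", "High-grade glioma", "HGG, BRAF V600E",
            snvs = snv_spec("BRAF", "p.V600E", 600)),
    planted("HGG-06", "High-grade glioma", "HGG, H3 wild type"),
    planted("HGG-07", "High-grade glioma", "DMG, H3 K28, TP53 activated",
            snvs = bind_rows(snv_spec("H3F3A", "p.K28M", 28),
                             snv_spec("TP53", "p.R273C", 273))),
    planted("HGG-08", "High-grade glioma", "DMG, H3 K28, TP53 loss",
            snvs = bind_rows(snv_spec("H3F3A", "p.K28M", 28),
                             snv_spec("TP53", "p.R175H", 175))),
    planted("LGG-01", lgg_dx, "LGG, KIAA1549-BRAF",
            fusions = "KIAA1549--BRAF"),
    planted("LGG-02", lgg_dx, "LGG, BRAF V600E, CDKN2A/B",
            snvs = snv_spec("BRAF", "p.V600E", 600),
            cnv = cnv_spec("gene", "CDKN2A", 0)),
    planted("LGG-03", lgg_dx, "LGG, NF1-somatic",
            snvs = snv_spec("NF1", "p.R1000*", 1000, consequence = "High")),
    planted("LGG-04", lgg_dx, "LGG, NF1-germline",
            predisposition = "NF-1"),
    planted("LGG-05", lgg_dx, "LGG, IDH",
            snvs = snv_spec("IDH1", "p.R132H", 132)),
    planted("LGG-06", lgg_dx, "LGG, H3",
            snvs = snv_spec("H3F3A", "p.K28M", 28)),
    planted("LGG-07", lgg_dx, "LGG, other MAPK",
            snvs = snv_spec("KRAS", "p.G12D", 12)),
    planted("LGG-08", lgg_dx, "LGG, RTK",
            fusions = "ETV6--NTRK2"),
    planted("LGG-09", lgg_dx, "LGG, FGFR",
            snvs = snv_spec("FGFR1", "p.N546K", 546)),
    planted("LGG-10", lgg_dx, "LGG, MYB/MYBL1",
            fusions = "MYB--QKI"),
    planted("LGG-11", lgg_dx, "LGG, wild type"),
    planted("LGG-12", lgg_dx, "LGG, To be classified", has_rna = FALSE),
    planted("SEGA-01", "Subependymal Giant Cell Astrocytoma (SEGA)",
            "SEGA, wild type"),
    planted("GNT-01", "Ganglioglioma", "GNT, KIAA1549-BRAF",
            free_text = "glioneuronal tumor",
            fusions = "KIAA1549--BRAF"),
    planted("EMB-01", "Embryonal Tumor with Multilayered Rosettes",
            "ETMR, C19MC altered",
            fusions = "TTYH1--C19MC",
            cnv = cnv_spec("gene", "C19MC", 12),
            overexpress = "LIN28A"),
    planted("EMB-02", pnet_dx, "ETMR, NOS",
            free_text = "embryonal tumor with multilayer rosettes, ros (who grade iv)",
            fusions = "TTYH1--C19MC",
            overexpress = "LIN28A"),
    planted("EMB-03", pnet_dx, "CNS HGNET-MN1",
            fusions = "MN1--BEND2"),
    planted("EMB-04", pnet_dx, "CNS HGNET-BCOR", bcor_itd = TRUE),
    planted("EMB-05", "Neuroblastoma", "CNS NB-FOXR2",
            site = "Posterior fossa", overexpress = "FOXR2"),
    planted("EMB-06", pnet_dx, "CNS EFT-CIC",
            fusions = "CIC--NUTM1"),
    planted("EMB-07", pnet_dx, "CNS embryonal, NOS"),
    planted("EPN-01", "Ependymoma", "EPN, ST RELA",
            fusions = "C11orf95--RELA"),
    planted("EPN-02", "Ependymoma", "EPN, ST YAP1",
            fusions = "YAP1--MAMLD1"),
    planted("EPN-03", "Ependymoma", "EPN, PF A",
            overexpress = "CXorf67"),
    planted("EPN-04", "Ependymoma", "EPN, PF B",
            overexpress = "IFT46",
            cnv = cnv_spec("arm", "6q", 1)),
    planted("EPN-05", "Ependymoma", "EPN, ST RELA",
            overexpress = "L1CAM"),
    planted("EPN-06", "Ependymoma", "EPN, ST YAP1",
            cnv = bind_rows(cnv_spec("arm", "11p", 1),
                            cnv_spec("arm", "11q", 3))),
    planted("EPN-07", "Ependymoma", "EPN, To be classified"),
    planted("CRANIO-01", "Craniopharyngioma", "CRANIO, PAP", age = 45,
            snvs = snv_spec("BRAF", "p.V600E", 600)),
    planted("CRANIO-02", "Craniopharyngioma", "CRANIO, ADAM", age = 10,
            snvs = snv_spec("CTNNB1", "p.S37F", 37)),
    planted("CRANIO-03", "Craniopharyngioma", "CRANIO, To be classified",
            age = 40),
    planted("NC-01", "Neurocytoma", "CNC", site = "Ventricles"),
    planted("NC-02", "Neurocytoma", "EVN", site = "Frontal Lobe"),
    planted("EWS-01", "Ewings Sarcoma", "EWS", fusions = "EWSR1--FLI1"),
    planted("MB-01", "Medulloblastoma", "MB, SHH",
            mb1 = "SHH", mb2 = "SHH"),
    planted("MB-02", "Medulloblastoma", "MB, WNT",
            mb1 = "WNT", mb2 = "WNT"),
    planted("MB-03", "Medulloblastoma", "MB, group 3",
            mb1 = "Group3", mb2 = "Group3"),
    planted("MB-04", "Medulloblastoma", "MB, group 4",
            mb1 = "Group4", mb2 = "Group4"),
    planted("MB-05", "Medulloblastoma", "MB, To be classified",
            mb1 = "Group3", mb2 = "Group4")
  )
}

broad_histology_of <- function(dx) {
  dplyr::case_when(
    grepl("High-grade glioma|pontine", dx) ~ "High-grade glioma",
    grepl("Low-grade|Ganglioglioma|SEGA|Subependymal", dx) ~
      "Low-grade glioma",
    grepl("Medulloblastoma|PNET|Embryonal|Neuroblastoma", dx) ~
      "Embryonal tumor",
    grepl("Ependymoma", dx) ~ "Ependymoma",
    grepl("Craniopharyngioma", dx) ~ "Tumor of sellar region",
    grepl("Neurocytoma", dx) ~ "Neuronal and mixed neuronal-glial tumor",
    grepl("Ewing", dx) ~ "Mesenchymal non-meningothelial tumor",
    TRUE ~ "Other"
  )
}

# SNV truth at the gene's synthetic locus: position = locus start + protein
# position, so co-gene variants stay distinct and MNV pairs adjacent.
snv_truth_rows <- function(sample_id, snvs) {
  if (is.null(snvs) || nrow(snvs) == 0) {
    return(NULL)
  }
  loc <- gene_locus(snvs$gene)
  tibble(
    sample_id = sample_id,
    gene = snvs$gene,
    protein_change = snvs$protein_change,
    protein_position = snvs$protein_position,
    consequence_class = snvs$consequence_class,
    chromosome = loc$chromosome,
    start = loc$start + snvs$protein_position,
    reference_allele = "A",
    alternate_allele = "T",
    vaf = snvs$vaf,
    mnv_group = NA_integer_
  )
}

cnv_truth_rows <- function(sample_id, cnv, genome, ploidy = 2L) {
  if (is.null(cnv) || nrow(cnv) == 0) {
    return(NULL)
  }
  models <- toy_gene_models()
  rows <- lapply(seq_len(nrow(cnv)), function(i) {
    if (cnv$kind[i] == "arm") {
      chrom <- paste0("chr", sub("[pq]$", "", cnv$target[i]))
      arm <- sub("^.*(p|q)$", "\\1", cnv$target[i])
      len <- genome$chromosomes$length[
        genome$chromosomes$chromosome == chrom
      ]
      boundary <- as.integer(len * TOY_P_FRACTION)
      if (arm == "p") {
        start <- 0L
        end <- boundary
      } else {
        start <- boundary
        end <- as.integer(len)
      }
    } else {
      g <- models[models$gene == cnv$target[i], , drop = FALSE]
      chrom <- g$chromosome
      start <- g$start - 20000L
      end <- g$end + 20000L
    }
    cn <- cnv$copy_number[i]
    tibble(
      sample_id = sample_id, chromosome = chrom,
      start = as.integer(start), end = as.integer(end),
      copy_number = cn,
      status = if (cn > ploidy) "gain" else if (cn < ploidy) "loss" else
        "neutral",
      ploidy = as.integer(ploidy)
    )
  })
  bind_rows(rows)
}

fusion_truth_rows <- function(sample_id, fusions) {
  if (is.null(fusions) || length(fusions) == 0) {
    return(NULL)
  }
  parts <- stringr::str_split_fixed(fusions, "--", 2)
  tibble(sample_id = sample_id, fusion_name = fusions,
         gene5 = parts[, 1], gene3 = parts[, 2])
}

#' Generate the synthetic cohort metadata and truth set
#'
#' Produces the histology table (one normal and at least one tumor
#' specimen per patient, with the clinical fields the subtyping rules
#' read) and the truth set: true somatic SNVs, CNV segments, fusions,
#' marker-gene overexpression, molecular subtype, MB classifier labels and
#' genetic sex per patient. In rule-coverage mode the cohort is the fixed
#' planted roster covering every subtyping branch; in random mode patients
#' are drawn from the configured cancer-group weights. The same
#' configuration and seed always yield identical tables.
#'
#' @param config A [cohort_config()].
#' @return List with `histology` (tibble) and `truth` (list of tibbles:
#'   `snv`, `cnv`, `fusion`, `overexpression`, `subtype`, `mb_scores`,
#'   `sex`, plus `bcor_itd`, a character vector of samples).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$mode == "rule-coverage") {
    roster <- rule_coverage_roster()
  } else {
    roster <- with_seed(derive_seed(config$seed, 1L),
                        random_roster(config))
  }
  n <- length(roster)
  empty_truth <- list(
    snv = snv_truth_rows("x", snv_spec("TP53", "p.R175H", 175))[0, ],
    cnv = cnv_truth_rows("x", cnv_spec("gene", "TP53", 0), toy_genome())[0, ],
    fusion = fusion_truth_rows("x", "A--B")[0, ],
    overexpression = tibble(sample_id = character(), gene = character()),
    subtype = tibble(sample_id = character(),
                     molecular_subtype = character()),
    mb_scores = tibble(sample_id = character(),
                       mb_classifier_1 = character(),
                       mb_classifier_2 = character()),
    sex = tibble(patient_id = character(), genetic_sex = character()),
    bcor_itd = character(0)
  )
  if (n == 0) {
    return(list(histology = histology_skeleton()[0, ], truth = empty_truth))
  }
  patient_ids <- sprintf("PT_%03d", seq_len(n))
  sample_ids <- sprintf("BS_%03d", seq_len(n))
  sexes <- with_seed(derive_seed(config$seed, 2L),
                     sample(c("Female", "Male"), n, replace = TRUE))
  descriptors <- with_seed(
    derive_seed(config$seed, 3L),
    sample(names(config$tumor_event_mix), n, replace = TRUE,
           prob = config$tumor_event_mix)
  )
  rows <- list()
  truth <- empty_truth
  for (i in seq_len(n)) {
    p <- roster[[i]]
    rows[[length(rows) + 1]] <- tibble(
      patient_id = patient_ids[i], sample_id = sample_ids[i],
      sample_type = "tumor", tumor_descriptor = descriptors[i],
      experimental_strategy = "WGS", RNA_library = "stranded",
      pathology_diagnosis = p$dx,
      pathology_free_text_diagnosis = p$free_text,
      primary_site = p$site, age_years = p$age,
      cancer_predispositions = p$predisposition,
      broad_histology = broad_histology_of(p$dx),
      reported_gender = sexes[i],
      has_dna = TRUE, has_rna = p$has_rna, planted_tag = p$tag
    )
    rows[[length(rows) + 1]] <- tibble(
      patient_id = patient_ids[i],
      sample_id = paste0(sample_ids[i], "-N"),
      sample_type = "normal", tumor_descriptor = NA_character_,
      experimental_strategy = "WGS", RNA_library = NA_character_,
      pathology_diagnosis = NA_character_,
      pathology_free_text_diagnosis = NA_character_,
      primary_site = NA_character_, age_years = p$age,
      cancer_predispositions = p$predisposition,
      broad_histology = NA_character_, reported_gender = sexes[i],
      has_dna = TRUE, has_rna = FALSE, planted_tag = NA_character_
    )
    truth$snv <- bind_rows(truth$snv, snv_truth_rows(sample_ids[i], p$snvs))
    truth$cnv <- bind_rows(truth$cnv,
                           cnv_truth_rows(sample_ids[i], p$cnv,
                                          config$genome))
    truth$fusion <- bind_rows(truth$fusion,
                              fusion_truth_rows(sample_ids[i], p$fusions))
    if (length(p$overexpress) > 0) {
      truth$overexpression <- bind_rows(
        truth$overexpression,
        tibble(sample_id = sample_ids[i], gene = p$overexpress)
      )
    }
    if (!is.na(p$label)) {
      truth$subtype <- bind_rows(truth$subtype, tibble(
        sample_id = sample_ids[i], molecular_subtype = p$label
      ))
    }
    if (!is.na(p$mb1)) {
      truth$mb_scores <- bind_rows(truth$mb_scores, tibble(
        sample_id = sample_ids[i], mb_classifier_1 = p$mb1,
        mb_classifier_2 = p$mb2
      ))
    }
    if (isTRUE(p$bcor_itd)) {
      truth$bcor_itd <- c(truth$bcor_itd, sample_ids[i])
    }
  }
  truth$sex <- tibble(patient_id = patient_ids, genetic_sex = sexes)
  # random mode injects adjacent MNV pairs at the configured rate
  if (config$mode == "random" && nrow(truth$snv) > 0 &&
      config$noise$mnv_rate > 0) {
    truth$snv <- with_seed(derive_seed(config$seed, 4L),
                           inject_mnv_pairs(truth$snv,
                                            config$noise$mnv_rate))
  }
  list(histology = bind_rows(rows), truth = truth)
}

histology_skeleton <- function() {
  tibble(
    patient_id = character(), sample_id = character(),
    sample_type = character(), tumor_descriptor = character(),
    experimental_strategy = character(), RNA_library = character(),
    pathology_diagnosis = character(),
    pathology_free_text_diagnosis = character(),
    primary_site = character(), age_years = double(),
    cancer_predispositions = character(), broad_histology = character(),
    reported_gender = character(), has_dna = logical(),
    has_rna = logical(), planted_tag = character()
  )
}

# Random-mode roster: clinically plausible draws without planted labels
# (subtype truth is only defined for the rule-coverage roster).
random_roster <- function(config) {
  if (config$n_patients == 0) {
    return(list())
  }
  groups <- sample(names(config$cancer_group_weights), config$n_patients,
                   replace = TRUE, prob = config$cancer_group_weights)
  dx_of <- c(
    "Low-grade glioma" = "Low-grade glioma/astrocytoma (WHO grade I/II)",
    "High-grade glioma" = "High-grade glioma",
    "Ependymoma" = "Ependymoma",
    "Medulloblastoma" = "Medulloblastoma"
  )
  snv_pool <- c("TP53", "ATRX", "NF1", "BRAF", "KRAS", "PIK3CA", "EGFR",
                "PPM1D", "CTNNB1", "SMARCB1")
  lapply(seq_len(config$n_patients), function(i) {
    n_snv <- sample(2:6, 1)
    genes <- sample(snv_pool, n_snv, replace = TRUE)
    pos <- sample(50:900, n_snv)
    snvs <- snv_spec(genes, paste0("p.X", pos, "Y"), pos,
                     consequence = sample(c("High", "Moderate", "Low"),
                                          n_snv, replace = TRUE),
                     vaf = stats::runif(n_snv, 0.1, 0.6))
    cnv <- NULL
    if (stats::runif(1) < 0.5) {
      arm <- sample(c("1q", "6q", "9p", "9q", "11p", "11q"), 1)
      cnv <- cnv_spec("arm", arm, sample(c(1L, 3L), 1))
    }
    planted(sprintf("RND-%03d", i),
            dx = unname(dx_of[groups[i]]), label = NA_character_,
            age = sample(1:18, 1), snvs = snvs, cnv = cnv,
            mb1 = if (groups[i] == "Medulloblastoma") "SHH" else NA,
            mb2 = if (groups[i] == "Medulloblastoma") "SHH" else NA)
  })
}

# Rewrite a fraction of single SNVs as adjacent 2-base pairs sharing an
# mnv_group, the raw material for caller representation differences.
inject_mnv_pairs <- function(snv, rate) {
  idx <- which(stats::runif(nrow(snv)) < rate)
  if (length(idx) == 0) {
    return(snv)
  }
  extra <- snv[idx, , drop = FALSE]
  extra$start <- extra$start + 1L
  extra$reference_allele <- "C"
  extra$alternate_allele <- "G"
  snv$mnv_group[idx] <- idx
  extra$mnv_group <- idx
  bind_rows(snv, extra) |>
    arrange(.data$sample_id, .data$chromosome, .data$start)
}
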