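#' Read a MAF-like somatic variant table
#'
#' Reads a tab-separated variant table using MAF v2.4 column names and returns
#' the package's internal call representation. Coordinates in the file are
#' 1-based inclusive (the MAF convention); they are carried as-is in the
#' `start` column since single-base substitutions dominate, and all interval
#' comparisons against 0-based half-open region files convert explicitly.
#'
#' @param path Path to a tab-separated file with at least the columns
#'   `Hugo_Symbol`, `Chromosome`, `Start_Position`, `Reference_Allele`,
#'   `Tumor_Seq_Allele2`, `Tumor_Sample_Barcode`. Optional columns
#'   `t_ref_count`, `t_alt_count`, `n_depth`, `gnomAD_AF`, `Consequence`,
#'   `Protein_position`, `HGVSp_Short`, `caller` are picked up when present.
#' @return A tibble of variant calls with internal column names
#'   (`sample_id`, `chromosome`, `start`, `reference_allele`,
#'   `alternate_allele`, ...). Chromosomes are normalized to the
#'   `"chr"`-prefixed dialect.
#' @export
read_maf <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  assert_columns(raw, c("Chromosome", "Start_Position", "Reference_Allele",
                        "Tumor_Seq_Allele2", "Tumor_Sample_Barcode"),
                 what = "MAF file")
  opt_chr <- function(col) {
    if (col %in% names(raw)) as.character(raw[[col]]) else NA_character_
  }
  opt_num <- function(col) {
    if (col %in% names(raw)) as.numeric(raw[[col]]) else NA_real_
  }
  tibble(
    sample_id = as.character(raw$Tumor_Sample_Barcode),
    chromosome = normalize_chromosome(raw$Chromosome),
    start = as.integer(raw$Start_Position),
    reference_allele = as.character(raw$Reference_Allele),
    alternate_allele = as.character(raw$Tumor_Seq_Allele2),
    caller = if ("caller" %in% names(raw)) as.character(raw$caller) else NA_character_,
    t_ref_count = opt_num("t_ref_count"),
    t_alt_count = opt_num("t_alt_count"),
    n_depth = opt_num("n_depth"),
    population_af = opt_num("gnomAD_AF"),
    consequence_class = opt_chr("Consequence"),
    hugo_symbol = opt_chr("Hugo_Symbol"),
    protein_position = suppressWarnings(as.integer(opt_chr("Protein_position"))),
    hgvsp_short = opt_chr("HGVSp_Short"),
    hotspot = if ("hotspot" %in% names(raw)) as.logical(raw$hotspot) else FALSE,
    tert_promoter = if ("tert_promoter" %in% names(raw)) {
      as.character(raw$tert_promoter)
    } else {
      "none"
    }
  )
}

#' Write variant calls as a MAF-like table
#'
#' @param calls A variant-call tibble (see [read_maf()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(calls, path) {
  out <- tibble(
    Hugo_Symbol = calls$hugo_symbol,
    Chromosome = calls$chromosome,
    Start_Position = calls$start,
    Reference_Allele = calls$reference_allele,
    Tumor_Seq_Allele2 = calls$alternate_allele,
    Tumor_Sample_Barcode = calls$sample_id,
    t_ref_count = calls$t_ref_count,
    t_alt_count = calls$t_alt_count,
    n_depth = calls$n_depth,
    gnomAD_AF = calls$population_af,
    Consequence = calls$consequence_class,
    Protein_position = calls$protein_position,
    HGVSp_Short = calls$hgvsp_short,
    caller = calls$caller,
    hotspot = calls$hotspot,
    tert_promoter = calls$tert_promoter
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a SEG-like copy-number segment table
#'
#' Columns: `sample_id`, `chromosome`, `start`, `end` (0-based half-open),
#' and any of `copy_number`, `status`, `log2_ratio`, `p_value`, `ploidy`,
#' `caller`.
#'
#' @param path Path to a tab-separated segment file.
#' @return A segment tibble.
#' @export
read_seg <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(raw, c("sample_id", "chromosome", "start", "end"),
                 what = "segment file")
  raw$chromosome <- normalize_chromosome(raw$chromosome)
  for (col in c("copy_number", "ploidy")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_integer_
  }
  for (col in c("log2_ratio", "p_value")) {
    if (!col %in% names(raw)) raw[[col]] <- NA_real_
  }
  if (!"status" %in% names(raw)) raw$status <- NA_character_
  if (!"caller" %in% names(raw)) raw$caller <- NA_character_
  as_tibble(raw)
}

#' Write a segment tibble as SEG-like TSV
#' @param segments Segment tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_seg <- function(segments, path) {
  readr::write_tsv(segments, path)
  invisible(path)
}

#' Read a BED file of genomic intervals
#'
#' @param path Path to a BED(3+) file (0-based half-open, no header).
#' @return A tibble with `chromosome`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  out <- tibble(
    chromosome = normalize_chromosome(raw$X1),
    start = as.integer(raw$X2),
    end = as.integer(raw$X3)
  )
  if (ncol(raw) >= 4) out$name <- as.character(raw$X4)
  out
}

#' Read a UCSC-style cytoband file
#'
#' Expects the `cytoBand.txt` layout: chromosome, start, end, band name
#' (e.g. `p11.2`), Giemsa stain; tab-separated, no header, 0-based half-open.
#'
#' @param path Path to the cytoband file.
#' @return A tibble with `chromosome`, `start`, `end`, `band`, `stain` and a
#'   derived `arm` column (`p`/`q` from the band name).
#' @export
read_cytobands <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chromosome", "start", "end",
                                             "band", "stain"),
                         show_col_types = FALSE)
  raw$chromosome <- normalize_chromosome(raw$chromosome)
  raw$arm <- substr(raw$band, 1, 1)
  as_tibble(raw)
}

#' Read a cohort histology/metadata table
#' @param path Path to a tab-separated histology file.
#' @return A tibble.
#' @export
read_histology <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_guess()))
}

#' Read an expression matrix with gene identifiers and symbols
#'
#' @param path Tab-separated file whose first two columns are `gene_id` and
#'   `gene_symbol`, followed by one column per sample.
#' @return A tibble (one row per gene identifier).
#' @export
read_expression <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(m, c("gene_id", "gene_symbol"), what = "expression matrix")
  m
}

#' The printed per-specimen TMB table for hypermutant patients
#'
#' Transcription of the published table of patients with at least one
#' hypermutant or ultra-hypermutant tumor or cell line: participant and
#' biospecimen identifiers, phase of therapy, specimen composition, cancer
#' predisposition, coding-region TMB (Mut/Mb) and molecular subtype.
#'
#' @return A tibble with one row per specimen (11 rows).
#' @export
hypermutant_tmb_table <- function() {
  readr::read_tsv(pedcns_extdata("hypermutant_tmb.tsv"),
                  show_col_types = FALSE)
}

#' The published molecular-subtype tally
#'
#' Transcription of the published per-subtype counts of patients and tumors
#' assigned each molecular subtype, by broad histology group.
#'
#' @return A tibble with columns `broad_histology`, `molecular_subtype`,
#'   `patients`, `tumors`.
#' @export
subtype_count_table <- function() {
  readr::read_tsv(pedcns_extdata("molecular_subtype_counts.tsv"),
                  show_col_types = FALSE)
}
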