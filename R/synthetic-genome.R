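# Miniature genome model backing the synthetic cohort. A handful of few-Mb
# chromosomes is enough to exercise every interval operation; all interval
# code is genome-agnostic, so nothing downstream depends on these sizes.

TOY_CHROM_LENGTHS <- c(
  chr1 = 12e6, chr2 = 20e6, chr5 = 3e6, chr6 = 10e6, chr9 = 10e6,
  chr11 = 10e6, chr17 = 5e6, chr19 = 6e6, chrX = 8e6, chrY = 2e6
)
# fraction of each chromosome assigned to the p arm
TOY_P_FRACTION <- 0.4

#' Miniature genome model for the synthetic cohort
#'
#' Ten small chromosomes (a few Mb each) with synthetic cytobands (two
#' bands per arm, p arm in the first 40% of the chromosome) and exclusion
#' intervals standing in for telomeric (50 kb at each end) and centromeric
#' (100 kb at the p/q boundary) regions.
#'
#' @return List with `chromosomes` (tibble `chromosome`, `length`),
#'   `cytobands` (UCSC-like tibble with `arm`), and `exclusions` (tibble of
#'   excluded intervals).
#' @export
toy_genome <- function() {
  chroms <- tibble(
    chromosome = names(TOY_CHROM_LENGTHS),
    length = as.integer(TOY_CHROM_LENGTHS)
  )
  bands <- bind_rows(lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    boundary <- as.integer(len * TOY_P_FRACTION)
    half_p <- as.integer(boundary / 2)
    half_q <- as.integer((len - boundary) / 2)
    tibble(
      chromosome = chroms$chromosome[i],
      start = c(0L, half_p, boundary, boundary + half_q),
      end = c(half_p, boundary, boundary + half_q, len),
      band = c("p12", "p11", "q11", "q12"),
      stain = c("gneg", "gpos50", "gneg", "gpos50")
    )
  }))
  bands$arm <- substr(bands$band, 1, 1)
  exclusions <- bind_rows(lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    boundary <- as.integer(len * TOY_P_FRACTION)
    tibble(
      chromosome = chroms$chromosome[i],
      start = c(0L, boundary - 50000L, len - 50000L),
      end = c(50000L, boundary + 50000L, len),
      name = c("telomere_p", "centromere", "telomere_q")
    )
  }))
  list(chromosomes = chroms, cytobands = bands, exclusions = exclusions)
}

#' Gene models of the miniature genome
#'
#' Single-exon gene intervals for the genes the subtyping and focal
#' copy-number rules reference (CDKN2A/B on 9p, TP53 on chr17, the C19MC
#' cluster on 19q), plus deterministic loci on chr2 for every other gene
#' the synthetic cohort can mutate, spaced 50 kb apart.
#'
#' @return Tibble with `gene`, `chromosome`, `start`, `end` (0-based
#'   half-open).
#' @export
toy_gene_models <- function() {
  placed <- tibble(
    gene = c("CDKN2A", "CDKN2B", "TP53", "C19MC"),
    chromosome = c("chr9", "chr9", "chr17", "chr19"),
    start = c(1000000L, 1020000L, 1000000L, 4000000L),
    end = c(1010000L, 1030000L, 1020000L, 4100000L)
  )
  others <- setdiff(SYNTHETIC_GENE_REGISTRY, placed$gene)
  generic <- tibble(
    gene = others,
    chromosome = "chr2",
    start = 200000L + 50000L * (seq_along(others) - 1L),
    end = 200000L + 50000L * (seq_along(others) - 1L) + 10000L
  )
  bind_rows(placed, generic)
}

# Every gene the synthetic truth can reference; chr2 loci are assigned by
# position in this vector, so the order is part of the generator contract.
SYNTHETIC_GENE_REGISTRY <- c(
  "ALK", "ARAF", "ARL4D", "ATRX", "BCOR", "BEND2", "BRAF", "C11orf95",
  "C19MC", "CDKN2A", "CDKN2B", "CIC", "CLDN1", "CTNNB1", "CXXC5",
  "CXorf67", "EGFR", "ETV6", "EWSR1", "FGFR1", "FGFR2", "FLI1", "FOXR2",
  "GPBP17", "H3F3A", "H3F3B", "HIST1H3B", "HIST1H3C", "HIST2H3C", "HRAS",
  "IDH1", "IFT46", "KIAA1549", "KIT", "KRAS", "L1CAM", "LIN28A", "MAML2",
  "MAMLD1", "MAP2K1", "MAP2K2", "MET", "MN1", "MYB", "MYBL1", "NF1",
  "NF2", "NRAS", "NTRK1", "NTRK2", "NTRK3", "NUTM1", "PATZ1", "PDGFRA",
  "PIK3CA", "PPM1D", "PTEN", "QKI", "RAF1", "RELA", "ROS1", "SMARCB1",
  "TAS2R1", "TERT", "TKTL1", "TP53", "TTYH1", "YAP1"
)

# 1-based position of a gene's synthetic coding locus; SNV truth records are
# placed at locus start + protein_position so MNV pairs stay adjacent.
gene_locus <- function(gene) {
  models <- toy_gene_models()
  idx <- match(gene, models$gene)
  if (anyNA(idx)) {
    stop("unknown synthetic gene(s): ",
         paste(gene[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  list(chromosome = models$chromosome[idx], start = models$start[idx] + 1L)
}
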