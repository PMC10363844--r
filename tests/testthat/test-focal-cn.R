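toy_bands <- tibble::tibble(
  chromosome = "chr1",
  start = c(0L, 1000000L, 2000000L, 3000000L),
  end = c(1000000L, 2000000L, 3000000L, 4000000L),
  band = c("p12", "p11", "q11", "q12"),
  stain = "gneg", arm = c("p", "p", "q", "q")
)

test_that("band status fractions measure covered length per direction", {
  segs <- tibble::tibble(
    sample_id = "S1", chromosome = "chr1",
    start = c(0L, 2000000L), end = c(1000000L, 2500000L),
    status = c("loss", "gain"), copy_number = c(1L, 3L), ploidy = 2L
  )
  out <- band_status_fractions(segs, toy_bands)
  expect_equal(out$loss_fraction, c(1, 0, 0, 0))
  expect_equal(out$gain_fraction, c(0, 0, 0.5, 0))
  expect_equal(out$callable_fraction, c(1, 0, 0.5, 0))
  # with no segments all fractions are zero
  empty <- band_status_fractions(segs[0, ], toy_bands)
  expect_true(all(empty$loss_fraction == 0 & empty$callable_fraction == 0))
  # overlapping cytobands are rejected
  bad <- toy_bands
  bad$start[2] <- 500000L
  expect_error(band_status_fractions(segs, bad), "overlap")
})

test_that("band coverage fractions match a per-base tally on a toy chromosome", {
  withr::with_seed(42, {
    n <- 30
    start <- sample.int(900000L, n)
    segs <- tibble::tibble(
      sample_id = "S1", chromosome = "chr1",
      start = start, end = start + sample.int(150000L, n),
      status = sample(c("gain", "loss"), n, replace = TRUE),
      copy_number = 3L, ploidy = 2L
    )
  })
  bands <- tibble::tibble(
    chromosome = "chr1", start = c(0L, 400000L),
    end = c(400000L, 1000000L), band = c("p11", "q11"),
    stain = "gneg", arm = c("p", "q")
  )
  out <- band_status_fractions(segs, bands)
  base_covered <- function(seg, lo, hi) {
    covered <- logical(hi - lo)
    for (i in seq_len(nrow(seg))) {
      s <- max(seg$start[i], lo)
      e <- min(seg$end[i], hi)
      if (e > s) covered[(s - lo + 1):(e - lo)] <- TRUE
    }
    mean(covered)
  }
  for (b in seq_len(nrow(bands))) {
    lo <- bands$start[b]
    hi <- bands$end[b]
    expect_equal(out$loss_fraction[b],
                 base_covered(segs[segs$status == "loss", ], lo, hi),
                 tolerance = 1e-12)
    expect_equal(out$gain_fraction[b],
                 base_covered(segs[segs$status == "gain", ], lo, hi),
                 tolerance = 1e-12)
    expect_equal(out$callable_fraction[b], base_covered(segs, lo, hi),
                 tolerance = 1e-12)
  }
})

test_that("arm fractions are band-length-weighted means", {
  bf <- tibble::tibble(
    chromosome = "chr1", band = c("p11", "p12"), arm = "p",
    start = c(0L, 1000000L), end = c(1000000L, 4000000L),
    region_length = c(1e6, 3e6),
    loss_fraction = c(1.0, 0.5), gain_fraction = 0,
    callable_fraction = c(1.0, 0.5)
  )
  out <- arm_fractions(bf)
  expect_equal(out$loss_fraction, 0.625)
  # single band: arm equals band
  single <- arm_fractions(bf[1, ])
  expect_equal(single$loss_fraction, 1.0)
  # uniform fractions pass through the weighted mean unchanged
  uniform <- bf
  uniform$loss_fraction <- 0.37
  uniform$callable_fraction <- 0.37
  expect_equal(arm_fractions(uniform)$loss_fraction, 0.37)
})

test_that("dominant status needs majority callability and a >0.9 fraction of callable", {
  f <- tibble::tibble(
    loss_fraction = c(0.9 * 0.95, 0.2, 0.8 * 0.50),
    gain_fraction = c(0, 0.1, 0.8 * 0.45),
    callable_fraction = c(0.9, 0.4, 0.8)
  )
  out <- dominant_status(f)
  expect_equal(out$status, c("loss", "uncallable", "callable-undetermined"))
  # total-length denominator mode is stricter
  tot <- dominant_status(f, denominator = "total")
  expect_equal(tot$status[1], "callable-undetermined")
})

test_that("gene-level status applies deep-deletion and autosome-only amplification rules", {
  exons <- tibble::tibble(
    chromosome = c("chr1", "chr1", "chrX"),
    start = c(100L, 5000L, 100L), end = c(1000L, 6000L, 1000L),
    gene = c("GENEA", "GENEB", "GENEX")
  )
  segs <- tibble::tibble(
    sample_id = "S1",
    chromosome = c("chr1", "chr1", "chrX"),
    start = c(0L, 4000L, 0L), end = c(2000L, 7000L, 2000L),
    copy_number = c(0L, 5L, 5L), status = "loss", ploidy = 2L
  )
  out <- gene_level_status(segs, exons)
  expect_equal(out$status[out$gene == "GENEA"], "deep deletion")
  expect_equal(out$status[out$gene == "GENEB"], "amplification")
  # X genes are capped at gain, never amplification
  expect_equal(out$status[out$gene == "GENEX"], "gain")
  # 5 copies at ploidy 3 is a gain, not amplification
  segs3 <- segs[2, ]
  segs3$ploidy <- 3L
  expect_equal(gene_level_status(segs3, exons)$status, "gain")
})

test_that("events are reported at exactly one level: arm, else band, else gene", {
  arms <- tibble::tibble(
    region = c("1p", "1q"), chromosome = "chr1", arm = c("p", "q"),
    region_length = 2e6,
    loss_fraction = c(0.95, 0.3), gain_fraction = c(0, 0.3),
    callable_fraction = c(1, 1),
    status = c("loss", "callable-undetermined")
  )
  bands <- tibble::tibble(
    chromosome = "chr1", band = c("p11", "q11", "q12"),
    arm = c("p", "q", "q"),
    start = c(0L, 2000000L, 3000000L),
    end = c(2000000L, 3000000L, 4000000L),
    region_length = 1e6,
    loss_fraction = 0, gain_fraction = c(0.95, 0.95, 0.2),
    callable_fraction = 1,
    status = c("gain", "gain", "callable-undetermined")
  )
  exons <- tibble::tibble(
    chromosome = "chr1", start = c(100000L, 3500000L),
    end = c(110000L, 3510000L), gene = c("GENEP", "GENEQ")
  )
  genes <- tibble::tibble(
    gene = c("GENEP", "GENEQ"), chromosome = "chr1",
    status = c("gain", "deep deletion"), copy_number = c(5L, 0L)
  )
  out <- most_focal_units(arms, bands, genes, exons)
  # dominant arm masks its bands and genes
  expect_true(any(out$level == "arm" & out$region == "1p"))
  expect_false(any(out$region %in% c("1p11", "GENEP")))
  # under the undetermined arm, the dominant band is reported
  expect_true(any(out$level == "cytoband" & out$region == "1q11"))
  # genes surface only under undetermined arm + undetermined band
  expect_true(any(out$level == "gene" & out$region == "GENEQ"))
  # each locus at exactly one level
  expect_equal(anyDuplicated(out$region), 0)
})
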