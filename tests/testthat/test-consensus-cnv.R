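test_that("per-caller segment pre-filters apply significance, PASS and noisy-file rules", {
  freec <- dplyr::bind_rows(
    make_segment(start = 0L, end = 10000L, p_value = 0.001,
                 caller = "controlfreec"),
    make_segment(start = 20000L, end = 30000L, p_value = 0.02,
                 caller = "controlfreec")
  )
  manta <- dplyr::bind_rows(
    make_segment(start = 0L, end = 10000L, caller = "manta",
                 filter = "PASS"),
    make_segment(start = 20000L, end = 30000L, caller = "manta",
                 filter = "MinQUAL")
  )
  cnvkit <- make_segment(caller = "cnvkit")
  out <- filter_caller_segments(freec, cnvkit, manta)
  expect_equal(out$freec$start, 0L)
  expect_equal(out$manta$start, 0L)
  expect_equal(nrow(out$cnvkit), 1)
  # a (sample, caller) file with 2,501 segments is dropped wholesale
  starts <- seq(0L, by = 1000L, length.out = 2501L)
  noisy <- make_segment(caller = "cnvkit")[rep(1, 2501), ]
  noisy$start <- starts
  noisy$end <- starts + 500L
  out2 <- filter_caller_segments(freec, noisy, manta)
  expect_equal(nrow(out2$cnvkit), 0)
  # at exactly 2,500 the file is kept
  out3 <- filter_caller_segments(freec, noisy[1:2500, ], manta)
  expect_equal(nrow(out3$cnvkit), 2500)
})

test_that("consensus intervals implement reciprocal-overlap and containment rules", {
  seg <- function(caller, start, end, status = "gain", cn = 3L) {
    make_segment(caller = caller, start = start, end = end,
                 status = status, copy_number = cn)
  }
  # 50% reciprocal overlap -> intersection span
  out <- consensus_intervals(dplyr::bind_rows(
    seg("controlfreec", 1000L, 2000L), seg("cnvkit", 1500L, 2500L)
  ))
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(1500L, 2000L))
  # 10% overlap -> nothing
  out <- consensus_intervals(dplyr::bind_rows(
    seg("controlfreec", 1000L, 2000L), seg("cnvkit", 1900L, 3000L)
  ))
  expect_equal(nrow(out), 0)
  # full containment (>90% of the smaller) -> the contained span
  out <- consensus_intervals(dplyr::bind_rows(
    seg("controlfreec", 1200L, 1400L), seg("cnvkit", 1000L, 2000L)
  ))
  expect_equal(c(out$start, out$end), c(1200L, 1400L))
  # opposite directions never pair
  out <- consensus_intervals(dplyr::bind_rows(
    seg("controlfreec", 1000L, 2000L, status = "gain"),
    seg("cnvkit", 1000L, 2000L, status = "loss", cn = 1L)
  ))
  expect_equal(nrow(out), 0)
  # single-caller input contributes nothing
  out <- consensus_intervals(seg("cnvkit", 1000L, 2000L))
  expect_equal(nrow(out), 0)
  # neutral consensus regions carry a missing copy number
  out <- consensus_intervals(dplyr::bind_rows(
    seg("controlfreec", 1000L, 2000L, status = "neutral", cn = 2L),
    seg("cnvkit", 1000L, 2000L, status = "neutral", cn = 2L)
  ))
  expect_true(is.na(out$copy_number))
})

test_that("consensus intervals match a brute-force all-pairs oracle on random segments", {
  for (seed in c(11, 12)) {
    segs <- random_segment_table(200, seed)
    out <- consensus_intervals(segs)
    # oracle: nested loops over all caller pairs within sample/chrom/status
    expected <- list()
    for (s in unique(segs$sample_id)) {
      for (ch in unique(segs$chromosome)) {
        for (st in unique(segs$status)) {
          g <- segs[segs$sample_id == s & segs$chromosome == ch &
                      segs$status == st, ]
          if (nrow(g) < 2) next
          for (i in seq_len(nrow(g) - 1)) {
            for (j in (i + 1):nrow(g)) {
              if (g$caller[i] == g$caller[j]) next
              ov_s <- max(g$start[i], g$start[j])
              ov_e <- min(g$end[i], g$end[j])
              ov <- ov_e - ov_s
              if (ov <= 0) next
              wi <- g$end[i] - g$start[i]
              wj <- g$end[j] - g$start[j]
              if ((ov / wi >= 0.5 && ov / wj >= 0.5) ||
                  ov / min(wi, wj) > 0.9) {
                expected[[length(expected) + 1]] <-
                  paste(s, ch, st, ov_s, ov_e)
              }
            }
          }
        }
      }
    }
    expect_setequal(
      paste(out$sample_id, out$chromosome, out$status, out$start, out$end),
      unique(unlist(expected))
    )
  }
})

test_that("merge/exclusion/size post-processing follows the stated order and rules", {
  cons <- tibble::tibble(
    sample_id = "S1", chromosome = "chr1",
    start = c(1000L, 12000L, 40000L, 100000L),
    end = c(5000L, 20000L, 42500L, 300000L),
    status = c("gain", "gain", "loss", "loss"),
    copy_number = c(3L, 3L, 1L, 1L), log2_ratio = NA_real_,
    ploidy = 2L, callers = "cnvkit,controlfreec"
  )
  out <- merge_and_filter(cons, exclusion = NULL)
  # gap of 7,000 merged; the 2,500 bp loss removed by the size filter
  expect_equal(nrow(out), 2)
  gains <- out[out$status == "gain", ]
  expect_equal(c(gains$start, gains$end), c(1000L, 20000L))
  # gain and loss 5,000 bp apart do not merge
  mixed <- cons[c(1, 3), ]
  mixed$start <- c(1000L, 10000L)
  mixed$end <- c(5000L, 50000L)
  out2 <- merge_and_filter(mixed, exclusion = NULL)
  expect_equal(nrow(out2), 2)
  expect_setequal(out2$status, c("gain", "loss"))
  # segments half-covered by exclusion regions are removed
  excl <- tibble::tibble(chromosome = "chr1", start = 100000L,
                         end = 210000L)
  out3 <- merge_and_filter(cons, exclusion = excl)
  expect_false(any(out3$start == 100000L))
  # input order never matters
  shuffled <- cons[c(3, 1, 4, 2), ]
  expect_equal(merge_and_filter(shuffled, exclusion = excl), out3)
})

test_that("final consensus segments are non-overlapping per sample and >= 3 kb", {
  for (seed in c(21, 22)) {
    segs <- random_segment_table(150, seed)
    out <- merge_and_filter(consensus_intervals(segs), exclusion = NULL)
    expect_true(all(out$end - out$start >= 3000))
    for (s in unique(out$sample_id)) {
      for (ch in unique(out$chromosome)) {
        g <- out[out$sample_id == s & out$chromosome == ch, ]
        g <- g[order(g$start), ]
        if (nrow(g) > 1) {
          expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
        }
      }
    }
  }
})

test_that("breakpoint densities use PASS SVs and non-zero log2 ratios over surveyed Mb", {
  cnv <- tibble::tibble(
    sample_id = "S1", chromosome = "chr1",
    start = c(0L, 10000L, 20000L), end = c(5000L, 15000L, 25000L),
    status = "gain", copy_number = 3L,
    log2_ratio = c(0, -0.5, 0.58), ploidy = 2L, callers = "x"
  )
  sv <- tibble::tibble(
    sample_id = rep("S1", 11),
    chromosome = "chr1", position = 1:11,
    filter = c(rep("PASS", 10), "LowQual")
  )
  out <- breakpoint_density(cnv, sv, surveyed_size_mb = 2800)
  expect_equal(out$sv_breaks, 10L)
  expect_equal(out$cnv_breaks, 2L)  # log2 ratio 0 is not a break
  expect_equal(out$sv_density, 10 / 2800, tolerance = 1e-12)
  expect_error(breakpoint_density(cnv, sv, 0), "positive")
})

test_that("chromothripsis input tiles every chromosome with ploidy-filled gaps", {
  genome <- tibble::tibble(chromosome = c("chr1", "chr2", "chrY"),
                           length = c(1000000L, 500000L, 200000L))
  cnv <- tibble::tibble(
    sample_id = "S1", chromosome = "chr1",
    start = c(100000L, 200000L, 300000L),
    end = c(200000L, 300000L, 400000L),
    copy_number = c(3L, 3L, NA_integer_), status = "gain",
    log2_ratio = NA_real_, ploidy = 2L, callers = "x"
  )
  ploidy <- tibble::tibble(sample_id = "S1", ploidy = 2L)
  out <- prepare_chromothripsis_input(cnv, ploidy, genome)
  # chrY excluded; every retained chromosome exactly tiled
  expect_false("chrY" %in% out$chromosome)
  for (ch in c("chr1", "chr2")) {
    g <- out[out$chromosome == ch, ]
    g <- g[order(g$start), ]
    expect_equal(g$start[1], 0)
    expect_equal(g$end[nrow(g)],
                 genome$length[genome$chromosome == ch])
    expect_equal(sum(g$end - g$start),
                 genome$length[genome$chromosome == ch])
    if (nrow(g) > 1) expect_true(all(g$start[-1] == g$end[-nrow(g)]))
  }
  chr1 <- out[out$chromosome == "chr1", ]
  chr1 <- chr1[order(chr1$start), ]
  # adjacent equal copy numbers merged: [100000,300000) CN 3 is one tile,
  # and the NA segment was set to ploidy and absorbed into the gap fill
  expect_equal(chr1$copy_number, c(2L, 3L, 2L))
  expect_equal(chr1$start, c(0L, 100000L, 300000L))
  # a chromosome with no calls is one whole-chromosome ploidy segment
  chr2 <- out[out$chromosome == "chr2", ]
  expect_equal(nrow(chr2), 1)
  expect_equal(chr2$copy_number, 2L)
})
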