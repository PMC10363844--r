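test_that("TMB counts coding consensus SNVs over the surveyed intersection", {
  caller_regions <- tibble::tibble(
    chromosome = "chr1", start = 0L, end = 2000000L
  )
  coding <- tibble::tibble(
    chromosome = "chr1", start = c(500000L, 1500000L),
    end = c(1200000L, 1800000L)
  )
  # surveyed = [5e5,1.2e6) + [1.5e6,1.8e6) = 1.0 Mb (brute-force check below)
  snvs <- dplyr::bind_rows(
    make_call(start = 600000L), make_call(start = 700000L),
    make_call(start = 800000L), make_call(start = 1600000L),
    make_call(start = 1700000L),
    make_call(start = 1300000L),          # outside coding: not counted
    make_call(start = 900000L, ref = "A", alt = "AT")  # indel: not counted
  )
  out <- compute_tmb(snvs, caller_regions, coding)
  expect_equal(out$surveyed_mb, 1.0)
  expect_equal(out$n_coding_snvs, 5L)
  expect_equal(out$tmb, 5.0)
  # brute-force per-base oracle for the denominator
  bases <- logical(2000000)
  bases[(500000 + 1):1200000] <- TRUE
  bases[(1500000 + 1):1800000] <- TRUE
  expect_equal(out$surveyed_mb, sum(bases) / 1e6)
  # invariance to splitting surveyed intervals
  split_coding <- tibble::tibble(
    chromosome = "chr1",
    start = c(500000L, 900000L, 1500000L, 1650000L),
    end = c(900000L, 1200000L, 1650000L, 1800000L)
  )
  expect_equal(compute_tmb(snvs, caller_regions, split_coding)$tmb, 5.0)
  # zero qualifying SNVs
  expect_equal(compute_tmb(snvs[0, ], caller_regions, coding,
                           samples = "S1")$tmb, 0)
  # disjoint regions make TMB undefined
  expect_error(compute_tmb(snvs, caller_regions,
                           dplyr::mutate(coding, chromosome = "chr9")),
               "intersect")
})

test_that("hypermutation classes use strict >10 and >100 thresholds", {
  expect_equal(
    classify_hypermutation(c(187.4, 35.9, 10, 100, 100.0001, 0)),
    c("ultra-hypermutant", "hypermutant", "normal", "hypermutant",
      "ultra-hypermutant", "normal")
  )
  expect_error(classify_hypermutation(-1), "non-negative")
})

test_that("gene tallies count distinct samples with qualifying nonsynonymous mutations", {
  snvs <- dplyr::bind_rows(
    make_call(sample_id = "S1", hugo_symbol = "TP53"),
    make_call(sample_id = "S2", hugo_symbol = "TP53"),
    make_call(sample_id = "S3", hugo_symbol = "TP53"),
    # second qualifying mutation in the same sample adds nothing
    make_call(sample_id = "S1", start = 200L, hugo_symbol = "TP53"),
    # VAF 4% is excluded by the >5% rule
    make_call(sample_id = "S1", hugo_symbol = "ATRX",
              t_ref_count = 96, t_alt_count = 4),
    # Low consequence class is not nonsynonymous
    make_call(sample_id = "S1", hugo_symbol = "NF1",
              consequence_class = "Low"),
    make_call(sample_id = "S1", hugo_symbol = "BRAF",
              consequence_class = "High")
  )
  out <- tally_mutated_genes(snvs)
  expect_equal(out$gene, c("TP53", "BRAF"))
  expect_equal(out$n_samples, c(3L, 1L))
  # deterministic tie-break: equal counts sort by gene name
  tied <- dplyr::bind_rows(
    make_call(sample_id = "S1", hugo_symbol = "ZZZ"),
    make_call(sample_id = "S1", hugo_symbol = "AAA")
  )
  expect_equal(tally_mutated_genes(tied)$gene, c("AAA", "ZZZ"))
  # top_n truncates after ranking
  expect_equal(nrow(tally_mutated_genes(snvs, top_n = 1)), 1)
})

test_that("co-occurrence scores follow I * (-log10 p) with Fisher p values", {
  # planted: A and B co-occur in 15 of 100 samples (20 each)
  samples <- paste0("S", 1:100)
  m <- matrix(FALSE, 2, 100, dimnames = list(c("A", "B"), samples))
  m["A", 1:20] <- TRUE
  m["B", c(1:15, 21:25)] <- TRUE
  out <- cooccurrence(m)
  expect_equal(out$n11, 15L)
  expect_equal(out$n10, 5L)
  expect_equal(out$n01, 5L)
  expect_equal(out$n00, 75L)
  expect_equal(out$p_value, oracle_fisher_p(15, 5, 5, 75),
               tolerance = 1e-10)
  expect_gt(out$odds_ratio, 1)
  expect_equal(out$score, -log10(out$p_value), tolerance = 1e-12)
  # perfectly exclusive genes score negative
  m2 <- matrix(FALSE, 2, 20, dimnames = list(c("A", "B"), paste0("S", 1:20)))
  m2["A", 1:10] <- TRUE
  m2["B", 11:20] <- TRUE
  out2 <- cooccurrence(m2)
  expect_equal(out2$p_value, oracle_fisher_p(0, 10, 10, 0),
               tolerance = 1e-10)
  expect_lt(out2$odds_ratio, 1)
  expect_equal(out2$score, log10(out2$p_value), tolerance = 1e-12)
  # independence with p = 1 gives score 0
  m3 <- matrix(FALSE, 2, 4, dimnames = list(c("A", "B"), paste0("S", 1:4)))
  m3["A", 1:2] <- TRUE
  m3["B", c(1, 3)] <- TRUE
  out3 <- cooccurrence(m3)
  expect_equal(out3$p_value, 1)
  expect_equal(out3$score, 0)
})

test_that("co-occurrence is symmetric in gene order and BH q values are monotone", {
  withr::with_seed(99, {
    m <- matrix(stats::runif(5 * 40) < 0.3, 5, 40,
                dimnames = list(paste0("G", 1:5), paste0("S", 1:40)))
  })
  out <- cooccurrence(m)
  swapped <- cooccurrence(m[rev(rownames(m)), ])
  key <- function(df) {
    paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b))
  }
  expect_equal(out$score[order(key(out))],
               swapped$score[order(key(swapped))], tolerance = 1e-12)
  ord <- order(out$p_value)
  expect_true(all(diff(out$q_value[ord]) >= -1e-12))
  expect_true(all(out$n11 + out$n10 + out$n01 + out$n00 == 40))
})

test_that("Fisher p values match the hypergeometric oracle on random tables", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(2:40, 1)
      a <- sample(0:n, 1)
      b <- sample(0:(n - a), 1)
      c <- sample(0:(n - a - b), 1)
      d <- n - a - b - c
      m <- matrix(FALSE, 2, n,
                  dimnames = list(c("A", "B"),
                                  paste0("S", seq_len(n))))
      if (a > 0) m[, seq_len(a)] <- TRUE
      if (b > 0) m["A", a + seq_len(b)] <- TRUE
      if (c > 0) m["B", a + b + seq_len(c)] <- TRUE
      out <- cooccurrence(m)
      expect_equal(out$p_value, oracle_fisher_p(a, b, c, d),
                   tolerance = 1e-10)
    }
  })
})
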