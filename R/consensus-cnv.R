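#' Pre-filter per-caller CNV segment tables
#'
#' Applies the caller-specific quality rules used before consensus building:
#' Control-FREEC segments must be significant (p < 0.01), Manta segments must
#' have passed all of the caller's filters, and any (sample, caller) table
#' with more than `max_segments` segments is dropped wholesale, since such
#' samples are noisy and of poor quality. The cap is applied after the
#' per-segment filters.
#'
#' @param freec,cnvkit,manta Per-caller segment tibbles (see [read_seg()]);
#'   `manta` needs a `filter` column with `"PASS"` for passing segments.
#' @param max_segments Per-sample segment count above which a caller's calls
#'   for that sample are discarded (default 2500).
#' @return A list of filtered tibbles named `freec`, `cnvkit`, `manta`, each
#'   with a `caller` column set.
#' @export
filter_caller_segments <- function(freec, cnvkit, manta, max_segments = 2500) {
  freec$caller <- "controlfreec"
  cnvkit$caller <- "cnvkit"
  manta$caller <- "manta"
  freec <- freec[!is.na(freec$p_value) & freec$p_value < 0.01, , drop = FALSE]
  if ("filter" %in% names(manta)) {
    manta <- manta[!is.na(manta$filter) & manta$filter == "PASS", ,
                   drop = FALSE]
  }
  drop_noisy <- function(seg) {
    counts <- table(seg$sample_id)
    noisy <- names(counts)[counts > max_segments]
    seg[!seg$sample_id %in% noisy, , drop = FALSE]
  }
  list(freec = drop_noisy(freec), cnvkit = drop_noisy(cnvkit),
       manta = drop_noisy(manta))
}

# Rounded mean copy number with half-integer ties broken toward ploidy.
round_cn_toward_ploidy <- function(cns, ploidy) {
  cns <- cns[!is.na(cns)]
  if (length(cns) == 0) {
    return(NA_integer_)
  }
  m <- mean(cns)
  lo <- floor(m)
  hi <- ceiling(m)
  if (lo == hi) {
    return(as.integer(lo))
  }
  if (is.na(ploidy)) {
    ploidy <- 2
  }
  if (abs(lo - ploidy) <= abs(hi - ploidy)) as.integer(lo) else as.integer(hi)
}

#' Build consensus CNV intervals from filtered per-caller segments
#'
#' Within each (sample, chromosome, direction) group — gain with gain, loss
#' with loss, neutral with neutral — every pair of segments from two
#' different callers contributes a consensus region when either (1) the pair
#' has reciprocal overlap of at least 50%, or (2) more than 90% of the
#' smaller segment is covered by the other caller's segment. The emitted
#' span is the intersection of the pair (the conservative common region). No
#' region supported by a single caller survives. Regions whose contributing
#' calls are copy-neutral get a missing copy number; otherwise the copy
#' number is the rounded mean of the pair's values with ties broken toward
#' the sample's ploidy.
#'
#' @param segments A list of per-caller segment tibbles (e.g. the output of
#'   [filter_caller_segments()]) or a single tibble with a `caller` column.
#' @param reciprocal Minimum reciprocal-overlap fraction (default 0.5).
#' @param coverage Minimum covered fraction of the smaller segment for the
#'   containment rule (default 0.9, exclusive).
#' @return Tibble of consensus regions with columns `sample_id`,
#'   `chromosome`, `start`, `end`, `status`, `copy_number`, `log2_ratio`,
#'   `ploidy`, `callers`. Regions from different caller pairs may still
#'   overlap; [merge_and_filter()] consolidates them.
#' @export
consensus_intervals <- function(segments, reciprocal = 0.5, coverage = 0.9) {
  seg <- if (is.data.frame(segments)) segments else bind_rows(segments)
  empty <- tibble(
    sample_id = character(), chromosome = character(),
    start = integer(), end = integer(), status = character(),
    copy_number = integer(), log2_ratio = double(), ploidy = integer(),
    callers = character()
  )
  if (nrow(seg) == 0) {
    return(empty)
  }
  assert_columns(seg, c("sample_id", "chromosome", "start", "end", "status",
                        "caller"), what = "segments")
  groups <- split(
    seg,
    paste(seg$sample_id, seg$chromosome, seg$status, sep = "\r")
  )
  out <- lapply(groups, function(g) {
    callers <- unique(g$caller)
    if (length(callers) < 2) {
      return(NULL)
    }
    res <- list()
    pairs <- utils::combn(sort(callers), 2, simplify = FALSE)
    for (pr in pairs) {
      a <- g[g$caller == pr[1], , drop = FALSE]
      b <- g[g$caller == pr[2], , drop = FALSE]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(a$start + 1L, a$end),
        IRanges::IRanges(b$start + 1L, b$end)
      )
      for (h in seq_along(hits)) {
        i <- S4Vectors::queryHits(hits)[h]
        j <- S4Vectors::subjectHits(hits)[h]
        ov_start <- max(a$start[i], b$start[j])
        ov_end <- min(a$end[i], b$end[j])
        ov <- ov_end - ov_start
        wa <- a$end[i] - a$start[i]
        wb <- b$end[j] - b$start[j]
        recip <- ov / wa >= reciprocal && ov / wb >= reciprocal
        contained <- ov / min(wa, wb) > coverage
        if (recip || contained) {
          ploidy <- a$ploidy[i] %||% NA_integer_
          cn <- if (identical(g$status[1], "neutral")) {
            NA_integer_
          } else {
            round_cn_toward_ploidy(c(a$copy_number[i], b$copy_number[j]),
                                   ploidy)
          }
          l2 <- mean(c(a$log2_ratio[i], b$log2_ratio[j]), na.rm = TRUE)
          res[[length(res) + 1]] <- tibble(
            sample_id = a$sample_id[i], chromosome = a$chromosome[i],
            start = as.integer(ov_start), end = as.integer(ov_end),
            status = g$status[1], copy_number = cn,
            log2_ratio = if (is.nan(l2)) NA_real_ else l2,
            ploidy = as.integer(ploidy),
            callers = paste(pr, collapse = ",")
          )
        }
      }
    }
    bind_rows(res)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(empty)
  }
  arrange(res, .data$sample_id, .data$chromosome, .data$start, .data$end)
}

#' Merge nearby consensus regions and apply exclusion and size filters
#'
#' Post-processing order is merge, exclusion filter, size filter. Regions of
#' the same direction within 10 kb of each other are merged into one (the
#' merged copy number is the rounded mean of members, ties toward ploidy).
#' Where merged gain and loss regions of one sample overlap — possible only
#' when callers disagree incoherently — the ambiguous overlap is removed
#' from both. Segments with half or more of their length inside the union of
#' exclusion intervals (immunoglobulin, telomeric, centromeric,
#' segment-duplicated regions) are then removed, and finally segments
#' shorter than `min_size` bp are removed.
#'
#' @param consensus Output of [consensus_intervals()].
#' @param exclusion Tibble of exclusion intervals (`chromosome`, `start`,
#'   `end`; 0-based half-open), or `NULL` for none.
#' @param merge_gap Maximum gap merged, in bp (default 10000).
#' @param exclusion_fraction Minimum overlap fraction triggering removal
#'   (default 0.5).
#' @param min_size Minimum retained segment length in bp (default 3000).
#' @return Tibble of final consensus segments, pairwise non-overlapping per
#'   sample, ordered by sample and position.
#' @export
merge_and_filter <- function(consensus, exclusion = NULL, merge_gap = 10000,
                             exclusion_fraction = 0.5, min_size = 3000) {
  if (nrow(consensus) == 0) {
    return(consensus)
  }
  groups <- split(
    consensus,
    paste(consensus$sample_id, consensus$chromosome, consensus$status,
          sep = "\r")
  )
  merged <- bind_rows(lapply(groups, function(g) {
    ir <- IRanges::IRanges(g$start + 1L, g$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    hits <- IRanges::findOverlaps(ir, red)
    member <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]
    bind_rows(lapply(seq_along(red), function(k) {
      rows <- g[member == k, , drop = FALSE]
      tibble(
        sample_id = rows$sample_id[1], chromosome = rows$chromosome[1],
        start = IRanges::start(red)[k] - 1L, end = IRanges::end(red)[k],
        status = rows$status[1],
        copy_number = round_cn_toward_ploidy(rows$copy_number,
                                             rows$ploidy[1]),
        log2_ratio = if (all(is.na(rows$log2_ratio))) NA_real_ else
          mean(rows$log2_ratio, na.rm = TRUE),
        ploidy = rows$ploidy[1],
        callers = paste(sort(unique(unlist(
          strsplit(rows$callers, ",", fixed = TRUE)
        ))), collapse = ",")
      )
    }))
  }))
  merged <- resolve_direction_conflicts(merged)
  if (!is.null(exclusion) && nrow(exclusion) > 0 && nrow(merged) > 0) {
    frac <- vapply(seq_len(nrow(merged)), function(i) {
      overlap_width(merged[i, ], exclusion) /
        (merged$end[i] - merged$start[i])
    }, numeric(1))
    merged <- merged[frac < exclusion_fraction, , drop = FALSE]
  }
  merged <- merged[merged$end - merged$start >= min_size, , drop = FALSE]
  arrange(merged, .data$sample_id, .data$chromosome, .data$start)
}

# Remove, from both sides, any region where a sample's merged gain and loss
# segments overlap; direction there is ambiguous.
resolve_direction_conflicts <- function(merged) {
  if (nrow(merged) == 0) {
    return(merged)
  }
  out <- lapply(split(merged, merged$sample_id), function(g) {
    gains <- g[g$status == "gain", , drop = FALSE]
    losses <- g[g$status == "loss", , drop = FALSE]
    if (nrow(gains) == 0 || nrow(losses) == 0) {
      return(g)
    }
    conflict <- suppressWarnings(IRanges::intersect(
      segments_to_granges(gains), segments_to_granges(losses)
    ))
    if (length(conflict) == 0) {
      return(g)
    }
    trim <- function(rows) {
      bind_rows(lapply(seq_len(nrow(rows)), function(i) {
        left <- GenomicRanges::setdiff(segments_to_granges(rows[i, ]),
                                       conflict)
        if (length(left) == 0) {
          return(rows[0, , drop = FALSE])
        }
        pieces <- rows[rep(i, length(left)), , drop = FALSE]
        pieces$start <- GenomicRanges::start(left) - 1L
        pieces$end <- GenomicRanges::end(left)
        pieces
      }))
    }
    bind_rows(trim(gains), trim(losses),
              g[!g$status %in% c("gain", "loss"), , drop = FALSE])
  })
  bind_rows(out)
}

#' Breakpoint densities per sample
#'
#' Two densities per sample, each expressed as breaks per Mb of effectively
#' surveyed genome: one from structural-variant breakpoints that passed all
#' caller filters, one from consensus copy-number segments whose absolute
#' log2 ratio exceeds log2(1) = 0 (a copy-number break).
#'
#' @param consensus_cnv Consensus segment tibble with `log2_ratio`.
#' @param sv_breakpoints Tibble with `sample_id` and `filter` columns, one
#'   row per breakpoint.
#' @param surveyed_size_mb Size in Mb of the effectively surveyed genome;
#'   must be positive.
#' @return Tibble with per-sample break counts and densities.
#' @export
breakpoint_density <- function(consensus_cnv, sv_breakpoints,
                               surveyed_size_mb) {
  if (!is.numeric(surveyed_size_mb) || length(surveyed_size_mb) != 1 ||
      is.na(surveyed_size_mb) || surveyed_size_mb <= 0) {
    stop("surveyed_size_mb must be a positive number", call. = FALSE)
  }
  sv_pass <- sv_breakpoints
  if ("filter" %in% names(sv_pass)) {
    sv_pass <- sv_pass[!is.na(sv_pass$filter) & sv_pass$filter == "PASS", ,
                       drop = FALSE]
  }
  cnv_break <- consensus_cnv[!is.na(consensus_cnv$log2_ratio) &
                               abs(consensus_cnv$log2_ratio) > 0, ,
                             drop = FALSE]
  samples <- sort(unique(c(consensus_cnv$sample_id, sv_breakpoints$sample_id)))
  tibble(
    sample_id = samples,
    sv_breaks = vapply(samples, function(s) {
      sum(sv_pass$sample_id == s)
    }, integer(1), USE.NAMES = FALSE),
    cnv_breaks = vapply(samples, function(s) {
      sum(cnv_break$sample_id == s)
    }, integer(1), USE.NAMES = FALSE)
  ) |>
    mutate(
      sv_density = .data$sv_breaks / surveyed_size_mb,
      cnv_density = .data$cnv_breaks / surveyed_size_mb
    )
}

#' Prepare gap-free copy-number input for chromothripsis detection
#'
#' Downstream chromothripsis callers require every base of every chromosome
#' to carry a copy number. Copy-neutral or uncalled regions are set to the
#' sample's ploidy, missing copy numbers are likewise replaced by ploidy,
#' and consecutive segments with equal copy number are merged.
#'
#' @param consensus_cnv Consensus segment tibble for one or more samples.
#' @param ploidy_by_sample Tibble with `sample_id` and `ploidy`.
#' @param genome Tibble with `chromosome` and `length` (bp) describing the
#'   genome model; chrY is excluded from tiling.
#' @return Tibble (`sample_id`, `chromosome`, `start`, `end`,
#'   `copy_number`) exactly tiling each chromosome for each sample.
#' @export
prepare_chromothripsis_input <- function(consensus_cnv, ploidy_by_sample,
                                         genome) {
  assert_columns(genome, c("chromosome", "length"), what = "genome model")
  chroms <- genome[genome$chromosome != "chrY", , drop = FALSE]
  out <- lapply(seq_len(nrow(ploidy_by_sample)), function(si) {
    sample <- ploidy_by_sample$sample_id[si]
    ploidy <- ploidy_by_sample$ploidy[si]
    seg <- consensus_cnv[consensus_cnv$sample_id == sample, , drop = FALSE]
    bind_rows(lapply(seq_len(nrow(chroms)), function(ci) {
      chrom <- chroms$chromosome[ci]
      len <- chroms$length[ci]
      s <- seg[seg$chromosome == chrom, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      bounds <- integer(0)
      cn <- integer(0)
      cursor <- 0L
      for (i in seq_len(nrow(s))) {
        seg_start <- max(s$start[i], cursor)
        seg_end <- min(s$end[i], len)
        if (seg_end <= seg_start) next
        if (seg_start > cursor) {
          bounds <- c(bounds, cursor, seg_start)
          cn <- c(cn, ploidy)
        }
        bounds <- c(bounds, seg_start, seg_end)
        cn <- c(cn, if (is.na(s$copy_number[i])) ploidy else s$copy_number[i])
        cursor <- seg_end
      }
      if (cursor < len) {
        bounds <- c(bounds, cursor, len)
        cn <- c(cn, ploidy)
      }
      tiles <- tibble(
        sample_id = sample, chromosome = chrom,
        start = bounds[seq(1, length(bounds), 2)],
        end = bounds[seq(2, length(bounds), 2)],
        copy_number = cn
      )
      # merge consecutive equal-copy-number tiles
      keep_new <- c(TRUE, tiles$copy_number[-1] !=
                      tiles$copy_number[-nrow(tiles)])
      tiles$run <- cumsum(keep_new)
      tiles |>
        group_by(.data$sample_id, .data$chromosome, .data$run) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  copy_number = .data$copy_number[1], .groups = "drop") |>
        select(-"run") |>
        select("sample_id", "chromosome", "start", "end", "copy_number")
    }))
  })
  bind_rows(out)
}
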