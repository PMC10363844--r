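#' Status call fractions per cytoband
#'
#' For every cytoband, computes the fraction of the band's length covered by
#' loss segments, by gain segments, and by any segment at all (the callable
#' fraction), for one sample's consensus copy-number segments.
#'
#' @param segments Consensus segments for a single sample (`chromosome`,
#'   `start`, `end`, `status`).
#' @param cytobands Cytoband tibble from [read_cytobands()]; bands must tile
#'   each chromosome without overlap.
#' @return Tibble with one row per band: `chromosome`, `band`, `arm`,
#'   `start`, `end`, `region_length`, `loss_fraction`, `gain_fraction`,
#'   `callable_fraction`.
#' @export
band_status_fractions <- function(segments, cytobands) {
  assert_columns(cytobands, c("chromosome", "start", "end", "band", "arm"),
                 what = "cytobands")
  by_chrom <- split(cytobands, cytobands$chromosome)
  for (cb in by_chrom) {
    cb <- cb[order(cb$start), , drop = FALSE]
    if (nrow(cb) > 1 && any(cb$start[-1] < cb$end[-nrow(cb)])) {
      stop("cytobands overlap on ", cb$chromosome[1], call. = FALSE)
    }
  }
  loss <- segments[!is.na(segments$status) & segments$status == "loss", ,
                   drop = FALSE]
  gain <- segments[!is.na(segments$status) & segments$status == "gain", ,
                   drop = FALSE]
  res <- lapply(seq_len(nrow(cytobands)), function(i) {
    bd <- cytobands[i, , drop = FALSE]
    len <- bd$end - bd$start
    in_band <- function(seg) {
      seg <- seg[seg$chromosome == bd$chromosome, , drop = FALSE]
      overlap_width(bd, seg) / len
    }
    tibble(
      chromosome = bd$chromosome, band = bd$band, arm = bd$arm,
      start = bd$start, end = bd$end, region_length = len,
      loss_fraction = in_band(loss),
      gain_fraction = in_band(gain),
      callable_fraction = in_band(segments)
    )
  })
  bind_rows(res)
}

#' Aggregate band fractions to chromosome arms
#'
#' Arm-level status call fractions are the band-length-weighted means of the
#' band fractions; arm membership comes from the band name's leading p/q.
#'
#' @param band_fractions Output of [band_status_fractions()].
#' @return Tibble with one row per (chromosome, arm) and the weighted
#'   `loss_fraction`, `gain_fraction`, `callable_fraction`, plus the arm's
#'   total `region_length`.
#' @export
arm_fractions <- function(band_fractions) {
  out <- band_fractions |>
    group_by(.data$chromosome, .data$arm) |>
    summarise(
      total_length = sum(.data$region_length),
      loss_fraction = sum(.data$loss_fraction * .data$region_length) /
        sum(.data$region_length),
      gain_fraction = sum(.data$gain_fraction * .data$region_length) /
        sum(.data$region_length),
      callable_fraction = sum(.data$callable_fraction *
                                .data$region_length) /
        sum(.data$region_length),
      .groups = "drop"
    ) |>
    rename(region_length = "total_length")
  if (any(out$region_length <= 0)) {
    stop("chromosome arm with zero total length", call. = FALSE)
  }
  out |>
    mutate(region = paste0(sub("^chr", "", .data$chromosome), .data$arm)) |>
    select("region", everything())
}

#' Dominant copy-number status of a region
#'
#' A region is uncallable when half or less of it is covered by any segment.
#' Otherwise a direction dominates when its status call fraction exceeds 0.9
#' — by default measured as a fraction of the callable portion, which
#' guarantees the dominant fraction exceeds every competing one; setting
#' `denominator = "total"` measures against the whole region length instead.
#' Regions that are callable but have no dominant direction are
#' "callable-undetermined".
#'
#' @param fractions Tibble with `loss_fraction`, `gain_fraction`,
#'   `callable_fraction` (one row per region, e.g. from [arm_fractions()] or
#'   [band_status_fractions()]).
#' @param threshold Dominance threshold (default 0.9, exclusive).
#' @param callable_min Minimum callable fraction (default 0.5, exclusive).
#' @param denominator `"callable"` (default) or `"total"`.
#' @return `fractions` with an added `status` column, one of `loss`, `gain`,
#'   `callable-undetermined`, `uncallable`.
#' @export
dominant_status <- function(fractions, threshold = 0.9, callable_min = 0.5,
                            denominator = c("callable", "total")) {
  denominator <- match.arg(denominator)
  denom <- if (denominator == "callable") {
    fractions$callable_fraction
  } else {
    rep(1, nrow(fractions))
  }
  loss_f <- ifelse(denom > 0, fractions$loss_fraction / denom, 0)
  gain_f <- ifelse(denom > 0, fractions$gain_fraction / denom, 0)
  status <- rep("callable-undetermined", nrow(fractions))
  status[loss_f > threshold] <- "loss"
  status[gain_f > threshold] <- "gain"
  status[fractions$callable_fraction <= callable_min] <- "uncallable"
  fractions$status <- status
  fractions
}

#' Gene-level copy-number status
#'
#' Overlaps consensus segments with gene exon models and classifies each
#' overlapping (segment, gene) pair: copy number 0 is a deep deletion; on
#' autosomes a copy number greater than twice the ploidy is an
#' amplification; otherwise the status is gain, loss or neutral by
#' comparison with ploidy. Sex-chromosome genes are never called amplified —
#' the amplification rule holds for autosomes only — and are capped at gain.
#'
#' @param segments Consensus segments for one sample with `copy_number` and
#'   `ploidy`.
#' @param gene_exons Tibble of exon intervals with `chromosome`, `start`,
#'   `end`, `gene` (0-based half-open).
#' @param ploidy Sample ploidy used when a segment's own `ploidy` is
#'   missing (default 2).
#' @return Tibble with one row per gene and per overlapping copy-number
#'   state: `gene`, `chromosome`, `status`, `copy_number`.
#' @export
gene_level_status <- function(segments, gene_exons, ploidy = 2) {
  assert_columns(gene_exons, c("chromosome", "start", "end", "gene"),
                 what = "gene models")
  if (nrow(segments) == 0 || nrow(gene_exons) == 0) {
    return(tibble(gene = character(), chromosome = character(),
                  status = character(), copy_number = integer()))
  }
  seg_gr <- GenomicRanges::GRanges(
    segments$chromosome, IRanges::IRanges(segments$start + 1L, segments$end)
  )
  exon_gr <- GenomicRanges::GRanges(
    gene_exons$chromosome,
    IRanges::IRanges(gene_exons$start + 1L, gene_exons$end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(seg_gr, exon_gr))
  if (length(hits) == 0) {
    return(tibble(gene = character(), chromosome = character(),
                  status = character(), copy_number = integer()))
  }
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  pl <- segments$ploidy[i]
  pl[is.na(pl)] <- ploidy
  cn <- segments$copy_number[i]
  autosome <- !segments$chromosome[i] %in% c("chrX", "chrY")
  status <- dplyr::case_when(
    !is.na(cn) & cn == 0 ~ "deep deletion",
    !is.na(cn) & autosome & cn > 2 * pl ~ "amplification",
    !is.na(cn) & cn > pl ~ "gain",
    !is.na(cn) & cn < pl ~ "loss",
    TRUE ~ "neutral"
  )
  tibble(
    gene = gene_exons$gene[j],
    chromosome = gene_exons$chromosome[j],
    status = status,
    copy_number = cn
  ) |>
    distinct()
}

#' Report each copy-number event at its most focal defensible unit
#'
#' Resolves the reporting hierarchy: an arm with dominant gain or loss is
#' reported as a single arm-level event and masks its bands and genes; under
#' a callable-undetermined arm, bands with dominant status are reported and
#' mask their genes; genes are reported only where both the arm and the band
#' are callable-undetermined. Uncallable arms and bands mask nothing below
#' them but are not themselves reported.
#'
#' @param arm_status Output of [dominant_status()] on arm fractions (must
#'   carry `chromosome`, `arm`, `status`).
#' @param band_status Output of [dominant_status()] on band fractions (must
#'   carry `chromosome`, `band`, `arm`, `status`).
#' @param gene_status Output of [gene_level_status()]; gene positions are
#'   located via `gene_exons`.
#' @param gene_exons Exon tibble used to place genes in bands.
#' @return Tibble (`region`, `level`, `status`) with `level` one of
#'   `arm`, `cytoband`, `gene`.
#' @export
most_focal_units <- function(arm_status, band_status, gene_status,
                             gene_exons) {
  arm_events <- arm_status |>
    filter(.data$status %in% c("gain", "loss")) |>
    transmute(
      region = paste0(sub("^chr", "", .data$chromosome), .data$arm),
      level = "arm", status = .data$status,
      chromosome = .data$chromosome, arm = .data$arm
    )
  open_arms <- arm_status |>
    filter(.data$status == "callable-undetermined")
  band_in_open_arm <- band_status |>
    semi_join(open_arms, by = c("chromosome", "arm"))
  band_events <- band_in_open_arm |>
    filter(.data$status %in% c("gain", "loss")) |>
    transmute(
      region = paste0(sub("^chr", "", .data$chromosome), .data$band),
      level = "cytoband", status = .data$status,
      chromosome = .data$chromosome, band = .data$band
    )
  open_bands <- band_in_open_arm |>
    filter(.data$status == "callable-undetermined")
  gene_events <- gene_status[0, , drop = FALSE]
  if (nrow(gene_status) > 0 && nrow(open_bands) > 0) {
    gene_pos <- gene_exons |>
      group_by(.data$gene, .data$chromosome) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop")
    in_open_band <- vapply(seq_len(nrow(gene_pos)), function(i) {
      b <- open_bands[open_bands$chromosome == gene_pos$chromosome[i], ,
                      drop = FALSE]
      any(b$start < gene_pos$end[i] & gene_pos$start < b$end)
    }, logical(1))
    gene_events <- gene_status |>
      semi_join(gene_pos[in_open_band, , drop = FALSE],
                by = c("gene", "chromosome")) |>
      filter(.data$status != "neutral")
  }
  bind_rows(
    arm_events |> select("region", "level", "status"),
    band_events |> select("region", "level", "status"),
    gene_events |> transmute(region = .data$gene, level = "gene",
                             status = .data$status)
  )
}

#' Run arm/band/gene focal copy-number resolution for one sample
#'
#' Convenience wrapper chaining [band_status_fractions()],
#' [arm_fractions()], [dominant_status()], [gene_level_status()] and
#' [most_focal_units()].
#'
#' @param segments Consensus segments of one sample.
#' @param cytobands Cytoband tibble.
#' @param gene_exons Exon tibble.
#' @param ploidy Sample ploidy.
#' @param denominator Passed to [dominant_status()].
#' @return List with `bands`, `arms`, `genes` and the combined `focal`
#'   table.
#' @export
focal_cn <- function(segments, cytobands, gene_exons, ploidy = 2,
                     denominator = "callable") {
  bands <- band_status_fractions(segments, cytobands) |>
    dominant_status(denominator = denominator)
  arms <- arm_fractions(bands) |>
    dominant_status(denominator = denominator)
  genes <- gene_level_status(segments, gene_exons, ploidy = ploidy)
  list(
    bands = bands, arms = arms, genes = genes,
    focal = most_focal_units(arms, bands, genes, gene_exons)
  )
}
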