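#' Decompose multi-nucleotide variants into consecutive SNVs
#'
#' Some callers report adjacent substitutions as one multi-nucleotide variant
#' (MNV) record while others emit each component base separately, so MNVs must
#' be decomposed before caller sets can be compared by exact position and
#' allele. Every k-base substitution (equal-length reference and alternate
#' alleles, k > 1) becomes up to k single-base records at consecutive
#' positions; positions where the reference base equals the alternate base are
#' dropped. Single-base substitutions and indels (unequal allele lengths) pass
#' through unchanged.
#'
#' @param calls A variant-call tibble (see [read_maf()]).
#' @return A tibble with MNVs replaced by their component SNVs; all other
#'   columns are copied from the parent record.
#' @export
#' @examples
#' calls <- tibble::tibble(
#'   sample_id = "S1", chromosome = "chr1", start = 100L,
#'   reference_allele = "AC", alternate_allele = "GT"
#' )
#' decompose_mnv(calls)
decompose_mnv <- function(calls) {
  assert_columns(calls, c("chromosome", "start", "reference_allele",
                          "alternate_allele"), what = "variant calls")
  if (nrow(calls) == 0) {
    return(calls)
  }
  len_ref <- nchar(calls$reference_allele)
  len_alt <- nchar(calls$alternate_allele)
  is_mnv <- len_ref == len_alt & len_ref > 1
  if (!any(is_mnv)) {
    return(calls)
  }
  mnv <- calls[is_mnv, , drop = FALSE]
  pieces <- lapply(seq_len(nrow(mnv)), function(i) {
    ref <- strsplit(mnv$reference_allele[i], "", fixed = TRUE)[[1]]
    alt <- strsplit(mnv$alternate_allele[i], "", fixed = TRUE)[[1]]
    keep <- which(ref != alt)
    if (length(keep) == 0) {
      return(mnv[0, , drop = FALSE])
    }
    out <- mnv[rep(i, length(keep)), , drop = FALSE]
    out$start <- mnv$start[i] + keep - 1L
    out$reference_allele <- ref[keep]
    out$alternate_allele <- alt[keep]
    out
  })
  bind_rows(calls[!is_mnv, , drop = FALSE], bind_rows(pieces))
}

#' Intersect three callers' variant calls into a consensus set
#'
#' A call is retained if and only if an identical
#' (chromosome, position, reference allele, alternate allele, sample) tuple
#' is present in all three caller inputs. Read counts and annotations of the
#' retained record come from the first caller in the fixed order
#' (strelka2, mutect2, lancet). A fourth caller's calls, if supplied, are
#' ignored for consensus: they are dominated by low-allele-fraction calls
#' unique to that caller.
#'
#' Inputs are MNV-decomposed internally (idempotent for already-decomposed
#' tables) so representation differences between callers cannot break the
#' exact-tuple comparison.
#'
#' @param strelka,mutect,lancet Per-caller variant-call tibbles.
#' @param vardict Optional fourth caller table; accepted and ignored.
#' @return The consensus call tibble (records taken from `strelka`), sorted
#'   by sample and position and unique per variant tuple.
#' @export
intersect_callers <- function(strelka, mutect, lancet, vardict = NULL) {
  strelka <- decompose_mnv(strelka)
  mutect <- decompose_mnv(mutect)
  lancet <- decompose_mnv(lancet)
  keep <- variant_key(strelka) %in% variant_key(mutect) &
    variant_key(strelka) %in% variant_key(lancet)
  out <- strelka[keep, , drop = FALSE]
  out <- arrange(out, .data$sample_id, .data$chromosome, .data$start,
                 .data$reference_allele, .data$alternate_allele)
  out[!duplicated(variant_key(out)), , drop = FALSE]
}

#' Read a hotspot database file
#'
#' The database has three entry classes: SNV hotspots keyed by gene and
#' protein position, splice-site hotspots keyed by gene and short protein
#' HGVS string, and indel hotspots keyed by gene and a protein-position
#' range.
#'
#' @param path Tab-separated file with columns `type`
#'   (`snv`/`splice`/`indel`), `hugo_symbol`, `protein_position`,
#'   `hgvsp_short`, `start_position`, `end_position`. Defaults to the small
#'   synthetic database bundled with the package.
#' @return A list with tibbles `snv`, `splice` and `indel`.
#' @export
read_hotspot_db <- function(path = pedcns_extdata("synthetic_hotspots.tsv")) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         na = c("", "NA"))
  list(
    snv = filter(raw, .data$type == "snv") |>
      select(hugo_symbol = "hugo_symbol",
             protein_position = "protein_position"),
    splice = filter(raw, .data$type == "splice") |>
      select(hugo_symbol = "hugo_symbol", hgvsp_short = "hgvsp_short"),
    indel = filter(raw, .data$type == "indel") |>
      select(hugo_symbol = "hugo_symbol", start_position = "start_position",
             end_position = "end_position")
  )
}

# Logical vector: does each call match the hotspot database?
hotspot_match <- function(calls, db) {
  n <- nrow(calls)
  if (n == 0) {
    return(logical(0))
  }
  is_snv <- nchar(calls$reference_allele) == nchar(calls$alternate_allele)
  snv_hit <- is_snv & paste(calls$hugo_symbol, calls$protein_position) %in%
    paste(db$snv$hugo_symbol, db$snv$protein_position)
  splice_hit <- paste(calls$hugo_symbol, calls$hgvsp_short) %in%
    paste(db$splice$hugo_symbol, db$splice$hgvsp_short)
  indel_hit <- rep(FALSE, n)
  is_indel <- !is_snv
  if (any(is_indel) && nrow(db$indel) > 0) {
    for (j in seq_len(nrow(db$indel))) {
      indel_hit <- indel_hit | (
        is_indel &
          !is.na(calls$hugo_symbol) &
          calls$hugo_symbol == db$indel$hugo_symbol[j] &
          !is.na(calls$protein_position) &
          calls$protein_position >= db$indel$start_position[j] &
          calls$protein_position <= db$indel$end_position[j]
      )
    }
  }
  out <- snv_hit | splice_hit | indel_hit
  out[is.na(out)] <- FALSE
  out
}

#' Flag calls that overlap the hotspot database
#'
#' Sets (or updates) the logical `hotspot` column by matching SNVs on
#' (gene, protein position), splice variants on (gene, HGVSp short) and
#' indels on the protein position falling within a hotspot range. Existing
#' `TRUE` flags (e.g. TERT promoter annotations) are preserved.
#'
#' @param calls A variant-call tibble.
#' @param db A hotspot database from [read_hotspot_db()].
#' @return `calls` with an updated `hotspot` column.
#' @export
flag_hotspots <- function(calls, db) {
  prior <- if ("hotspot" %in% names(calls)) {
    tidyr::replace_na(calls$hotspot, FALSE)
  } else {
    rep(FALSE, nrow(calls))
  }
  calls$hotspot <- prior | hotspot_match(calls, db)
  calls
}

#' Rescue hotspot calls from the union of callers
#'
#' Builds the hotspot call set: the union, over the three consensus-eligible
#' callers, of calls matching the hotspot database. A single caller's support
#' suffices here, unlike the three-way consensus, because curated hotspots
#' carry strong prior evidence. The result is a separate call set and is not
#' merged into the consensus.
#'
#' @param all_caller_calls One tibble (or a list of tibbles, bound together)
#'   holding calls from any combination of callers. If a `caller` column is
#'   present, only strelka2/mutect2/lancet records are eligible.
#' @param db A hotspot database from [read_hotspot_db()].
#' @return Tibble of unique hotspot calls (`hotspot` set to `TRUE`),
#'   de-duplicated per variant tuple with caller priority
#'   strelka2 > mutect2 > lancet.
#' @export
rescue_hotspots <- function(all_caller_calls, db) {
  calls <- if (is.data.frame(all_caller_calls)) {
    all_caller_calls
  } else {
    bind_rows(all_caller_calls)
  }
  if (nrow(calls) == 0) {
    return(calls)
  }
  if ("caller" %in% names(calls)) {
    eligible <- is.na(calls$caller) |
      calls$caller %in% c("strelka2", "mutect2", "lancet")
    calls <- calls[eligible, , drop = FALSE]
  }
  hits <- calls[hotspot_match(calls, db), , drop = FALSE]
  if (nrow(hits) == 0) {
    hits$hotspot <- logical(0)
    return(hits)
  }
  hits$hotspot <- TRUE
  priority <- match(hits$caller, c("strelka2", "mutect2", "lancet"))
  priority[is.na(priority)] <- 4L
  hits <- hits[order(variant_key(hits), priority), , drop = FALSE]
  hits <- hits[!duplicated(variant_key(hits)), , drop = FALSE]
  arrange(hits, .data$sample_id, .data$chromosome, .data$start)
}

#' Remove germline-like variants
#'
#' Non-hotspot calls with a matched-normal depth of 7 or less, or a
#' population allele frequency above 0.001, are removed as likely germline
#' contamination; hotspot-flagged calls are always retained. A missing
#' population frequency is treated as 0 (absence of evidence that the allele
#' is common), and a missing normal depth does not trigger the filter.
#'
#' @param calls A variant-call tibble with `hotspot`, `n_depth`,
#'   `population_af` columns.
#' @return Filtered tibble. The operation is idempotent.
#' @export
filter_germline_like <- function(calls) {
  assert_columns(calls, c("n_depth", "population_af"), what = "variant calls")
  hotspot <- if ("hotspot" %in% names(calls)) {
    tidyr::replace_na(calls$hotspot, FALSE)
  } else {
    rep(FALSE, nrow(calls))
  }
  af <- tidyr::replace_na(calls$population_af, 0)
  depth_bad <- !is.na(calls$n_depth) & calls$n_depth <= 7
  calls[hotspot | !(depth_bad | af > 0.001), , drop = FALSE]
}

# hg38 TERT promoter coordinates of the two recurrent activating mutations.
TERT_C228T_POS <- 1295113L
TERT_C250T_POS <- 1295135L

#' Annotate TERT promoter hotspot mutations
#'
#' Calls at chr5:1295113 are flagged `C228T` and calls at chr5:1295135 are
#' flagged `C250T` (hg38 coordinates, 66 and 88 bp upstream of the TERT
#' transcription start site). Flagged calls count as hotspots and therefore
#' survive the germline-like filter.
#'
#' @param calls A variant-call tibble.
#' @return `calls` with `tert_promoter` and `hotspot` columns updated.
#' @export
annotate_tert_promoter <- function(calls) {
  if (nrow(calls) == 0) {
    return(calls)
  }
  if (!"tert_promoter" %in% names(calls)) {
    calls$tert_promoter <- "none"
  }
  calls$tert_promoter[is.na(calls$tert_promoter)] <- "none"
  on5 <- calls$chromosome == "chr5"
  calls$tert_promoter[on5 & calls$start == TERT_C228T_POS] <- "C228T"
  calls$tert_promoter[on5 & calls$start == TERT_C250T_POS] <- "C250T"
  if (!"hotspot" %in% names(calls)) {
    calls$hotspot <- FALSE
  }
  calls$hotspot <- tidyr::replace_na(calls$hotspot, FALSE) |
    calls$tert_promoter != "none"
  calls
}

#' Run the full consensus SNV workflow
#'
#' Per caller: decompose MNVs, annotate TERT promoter positions, flag
#' hotspots, and drop germline-like calls. Then intersect the three callers
#' into the consensus set and build the separately-reported hotspot-rescued
#' set from the union of callers.
#'
#' @param strelka,mutect,lancet Per-caller variant-call tibbles.
#' @param vardict Optional fourth caller table, ignored for consensus.
#' @param hotspot_db Hotspot database from [read_hotspot_db()];
#'   `NULL` skips hotspot flagging/rescue.
#' @return List with elements `consensus` and `hotspot`.
#' @export
consensus_snv <- function(strelka, mutect, lancet, vardict = NULL,
                          hotspot_db = read_hotspot_db()) {
  prep <- function(calls, caller) {
    if (!"caller" %in% names(calls) || all(is.na(calls$caller))) {
      calls$caller <- caller
    }
    calls <- decompose_mnv(calls)
    calls <- annotate_tert_promoter(calls)
    if (!is.null(hotspot_db)) {
      calls <- flag_hotspots(calls, hotspot_db)
    }
    filter_germline_like(calls)
  }
  strelka <- prep(strelka, "strelka2")
  mutect <- prep(mutect, "mutect2")
  lancet <- prep(lancet, "lancet")
  hotspot <- if (is.null(hotspot_db)) {
    strelka[0, , drop = FALSE]
  } else {
    rescue_hotspots(bind_rows(strelka, mutect, lancet), hotspot_db)
  }
  list(
    consensus = intersect_callers(strelka, mutect, lancet),
    hotspot = hotspot
  )
}
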