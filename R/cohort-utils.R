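#' Estimate germline genetic sex from sex-chromosome read counts
#'
#' The summary statistic is the fraction of length-normalized
#' sex-chromosome reads attributed to the Y chromosome:
#' f = normY / (normX + normY) with normC = mapped reads on C / length of C.
#' Fractions below 0.2 clearly delineate females; fractions above 0.4 mark
#' predicted males; the inclusive range 0.2-0.4 is called Unknown.
#' Normalization by chromosome length can be disabled to inspect the raw
#' read fraction.
#'
#' @param stats Tibble with `sample_id`, `x_mapped_reads`,
#'   `y_mapped_reads`, `x_length`, `y_length` and optionally
#'   `reported_gender`.
#' @param normalize Divide read counts by chromosome length (default
#'   `TRUE`).
#' @return `stats` with `y_fraction` and `germline_sex_estimate` columns;
#'   when `reported_gender` is present, a `discordant` flag comparing the
#'   call against it.
#' @export
estimate_germline_sex <- function(stats, normalize = TRUE) {
  assert_columns(stats, c("sample_id", "x_mapped_reads", "y_mapped_reads",
                          "x_length", "y_length"), what = "read stats")
  if (any(stats$x_length <= 0 | stats$y_length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (any(stats$x_mapped_reads < 0 | stats$y_mapped_reads < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  nx <- if (normalize) stats$x_mapped_reads / stats$x_length else
    as.numeric(stats$x_mapped_reads)
  ny <- if (normalize) stats$y_mapped_reads / stats$y_length else
    as.numeric(stats$y_mapped_reads)
  if (any(nx + ny == 0)) {
    stop("zero total normalized sex-chromosome reads", call. = FALSE)
  }
  f <- ny / (nx + ny)
  stats$y_fraction <- f
  stats$germline_sex_estimate <- dplyr::case_when(
    f < 0.2 ~ "Female",
    f > 0.4 ~ "Male",
    TRUE ~ "Unknown"
  )
  if ("reported_gender" %in% names(stats)) {
    stats$discordant <- !is.na(stats$reported_gender) &
      stats$germline_sex_estimate != "Unknown" &
      stats$germline_sex_estimate != stats$reported_gender
  }
  stats
}

# Deterministic per-patient RNG stream: the tie-break draw for one patient
# never changes when other patients are added or removed.
patient_seed <- function(seed, patient_id) {
  h <- sum(utf8ToInt(patient_id) * seq_along(utf8ToInt(patient_id)))
  (as.integer(seed) + (h %% 1000003L)) %% .Machine$integer.max
}

#' Select one independent specimen per patient
#'
#' Analyses that assume sample independence need a single representative
#' specimen per individual. Specimens are prioritized as primary tumors
#' first, then whole-genome sequencing over other strategies; remaining ties
#' are broken by a seeded random choice namespaced by patient identifier,
#' so the selection is reproducible and adding a patient never changes
#' another patient's pick. Patients with no tumor specimen are excluded
#' with a warning.
#'
#' @param histology Histology tibble with `patient_id`, `sample_id`,
#'   `sample_type` (`"tumor"`/`"normal"`), `tumor_descriptor` and
#'   `experimental_strategy` columns.
#' @param seed Integer seed for the tie-break draws.
#' @return Tibble, a subset of `histology` rows, one per eligible patient.
#' @export
select_independent_samples <- function(histology, seed = 2023L) {
  assert_columns(histology, c("patient_id", "sample_id", "tumor_descriptor",
                              "experimental_strategy"),
                 what = "histology table")
  tumors <- histology
  if ("sample_type" %in% names(tumors)) {
    tumors <- tumors[tumors$sample_type == "tumor", , drop = FALSE]
  }
  dropped <- setdiff(unique(histology$patient_id),
                     unique(tumors$patient_id))
  if (length(dropped) > 0) {
    warning(length(dropped), " patient(s) with no tumor specimen excluded",
            call. = FALSE)
  }
  picks <- lapply(split(tumors, tumors$patient_id), function(g) {
    score <- (g$tumor_descriptor %in% c("primary", "Initial CNS Tumor",
                                        "initial CNS tumor")) * 2L +
      (g$experimental_strategy == "WGS") * 1L
    g <- g[score == max(score), , drop = FALSE]
    if (nrow(g) == 1) {
      return(g)
    }
    g <- g[order(g$sample_id), , drop = FALSE]
    rng <- with_seed(patient_seed(seed, g$patient_id[1]),
                     sample.int(nrow(g), 1))
    g[rng, , drop = FALSE]
  })
  bind_rows(picks) |> arrange(.data$patient_id)
}
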