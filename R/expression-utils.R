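#' Collapse an expression matrix to unique gene symbols
#'
#' Gene symbols frequently map to several Ensembl-style gene identifiers.
#' Rows with zero expression in every sample are removed first, then, for
#' each symbol with multiple surviving identifiers, only the identifier with
#' the maximum mean expression across samples is retained, on the assumption
#' that the highest-expressed identifier best represents the gene. Ties are
#' broken by the lexicographically smallest identifier for determinism.
#'
#' @param m Expression tibble: `gene_id`, `gene_symbol`, then one numeric
#'   column per sample (FPKM or TPM).
#' @return A tibble with unique `gene_symbol` values. Idempotent and never
#'   larger than the input.
#' @export
collapse_to_symbols <- function(m) {
  assert_columns(m, c("gene_id", "gene_symbol"), what = "expression matrix")
  sample_cols <- setdiff(names(m), c("gene_id", "gene_symbol"))
  vals <- as.matrix(m[, sample_cols, drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) {
    stop("expression values must be non-negative", call. = FALSE)
  }
  expressed <- rowSums(vals, na.rm = TRUE) > 0
  m <- m[expressed, , drop = FALSE]
  vals <- vals[expressed, , drop = FALSE]
  m$.mean <- rowMeans(vals, na.rm = TRUE)
  m |>
    arrange(.data$gene_symbol, desc(.data$.mean), .data$gene_id) |>
    distinct(.data$gene_symbol, .keep_all = TRUE) |>
    select(-".mean") |>
    arrange(.data$gene_symbol)
}

#' Cohort z-scores for a gene's expression
#'
#' z = (x - mu) / sigma, with mu and sigma computed over the stated sample
#' subset. Sigma is the sample (n-1) standard deviation by default. Samples
#' of different RNA library types should never be mixed in one call; the
#' caller is responsible for subsetting to a single library type.
#'
#' @param m Collapsed expression tibble (unique `gene_symbol`).
#' @param gene_symbol Gene to score.
#' @param sample_subset Character vector of sample columns defining the
#'   cohort; defaults to all sample columns.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Named numeric vector of z-scores, one per sample in the subset.
#' @export
expression_zscore <- function(m, gene_symbol, sample_subset = NULL,
                              sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  sample_cols <- setdiff(names(m), c("gene_id", "gene_symbol"))
  sample_subset <- sample_subset %||% sample_cols
  missing <- setdiff(sample_subset, sample_cols)
  if (length(missing) > 0) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  row <- m[m$gene_symbol == gene_symbol, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("gene symbol '", gene_symbol, "' matches ", nrow(row),
         " rows (need exactly 1)", call. = FALSE)
  }
  x <- as.numeric(row[1, sample_subset])
  names(x) <- sample_subset
  mu <- mean(x)
  sigma <- stats::sd(x)
  if (sd_type == "population") {
    sigma <- sqrt(mean((x - mu)^2))
  }
  if (is.na(sigma) || sigma == 0) {
    stop("zero variance for '", gene_symbol,
         "' over the given subset; z-score undefined", call. = FALSE)
  }
  (x - mu) / sigma
}

#' Z-scores for several genes at once
#'
#' Convenience wrapper around [expression_zscore()] returning a genes-by-
#' samples matrix; genes absent from the matrix or with zero variance yield
#' a row of `NA` instead of an error, which suits rule engines that treat
#' missing markers as no evidence.
#'
#' @inheritParams expression_zscore
#' @param gene_symbols Character vector of genes.
#' @return Numeric matrix, genes by samples.
#' @export
expression_zscore_matrix <- function(m, gene_symbols, sample_subset = NULL) {
  sample_cols <- setdiff(names(m), c("gene_id", "gene_symbol"))
  sample_subset <- sample_subset %||% sample_cols
  out <- matrix(NA_real_, nrow = length(gene_symbols),
                ncol = length(sample_subset),
                dimnames = list(gene_symbols, sample_subset))
  for (g in gene_symbols) {
    z <- tryCatch(expression_zscore(m, g, sample_subset),
                  error = function(e) NULL)
    if (!is.null(z)) {
      out[g, ] <- z
    }
  }
  out
}
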