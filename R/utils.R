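#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

#' Normalize chromosome names to the "chr"-prefixed dialect
#'
#' All tabular inputs are normalized on read so that `"5"`, `"chr5"` and
#' `"Chr5"` compare equal downstream.
#'
#' @param x Character vector of chromosome names.
#' @return Character vector with a lowercase `"chr"` prefix.
#' @export
#' @examples
#' normalize_chromosome(c("5", "chr5", "ChrX"))
normalize_chromosome <- function(x) {
  x <- as.character(x)
  paste0("chr", sub("^[Cc]hr", "", x))
}

# Single string key identifying a variant; exact-tuple comparisons everywhere
# use this so consensus logic cannot drift from the stated identity fields.
variant_key <- function(calls) {
  paste(calls$sample_id, calls$chromosome, calls$start,
        calls$reference_allele, calls$alternate_allele, sep = "\r")
}

# data.frame (chromosome, start, end; 0-based half-open) -> GRanges
segments_to_granges <- function(df) {
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chromosome,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# GRanges -> tibble with 0-based half-open start/end
granges_to_segments <- function(gr) {
  tibble(
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

# Total number of bases of `df` intervals falling inside `regions` intervals,
# both 0-based half-open tibbles. Used for coverage-fraction computations.
overlap_width <- function(df, regions) {
  if (nrow(df) == 0 || nrow(regions) == 0) {
    return(0)
  }
  hit <- suppressWarnings(IRanges::intersect(
    segments_to_granges(df),
    GenomicRanges::reduce(segments_to_granges(regions))
  ))
  sum(as.numeric(GenomicRanges::width(hit)))
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state:
# seeds stay explicit function arguments and never leak into global state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Path to a bundled reference or fixture table
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
pedcns_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "pedcns")))
  }
  path <- system.file("extdata", file, package = "pedcns")
  if (!nzchar(path)) {
    stop("no bundled file named '", file, "'", call. = FALSE)
  }
  path
}
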