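#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange mutate filter select group_by summarise ungroup
#'   bind_rows bind_cols left_join n row_number
#' @importFrom generics tidy glance augment
#' @importFrom ggplot2 autoplot
NULL

#' Normalize an interval table
#'
#' Interval tables are plain tibbles with `chrom`, `start`, `end` columns in
#' 0-based half-open coordinates (BED convention). This validates the columns,
#' coerces types and sorts by (chrom, start, end).
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param what Label used in error messages.
#' @return A tibble sorted by (chrom, start, end).
#' @export
as_intervals <- function(x, what = "intervals") {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x))) {
    abort(sprintf("%s must have columns chrom, start, end", what))
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  if (any(x$start >= x$end)) {
    abort(sprintf("%s: every interval needs start < end (half-open)", what))
  }
  arrange(x, .data$chrom, .data$start, .data$end)
}

## GRanges from a 0-based half-open tibble (internal; 1-based closed inside).
intervals_to_gr <- function(x, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
  if (!is.null(seqlengths)) {
    GenomicRanges::seqlevels(gr) <- names(seqlengths)
    GenomicRanges::seqlengths(gr) <- seqlengths
  }
  gr
}

gr_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  )
}

## Sequences are handled as named character vectors or Biostrings sets.
as_string_set <- function(sequence) {
  if (inherits(sequence, "DNAStringSet")) return(sequence)
  if (is.character(sequence)) {
    if (is.null(names(sequence)) && length(sequence) == 1L) {
      names(sequence) <- "seq"
    }
    return(Biostrings::DNAStringSet(sequence))
  }
  abort("sequence must be a named character vector or a DNAStringSet")
}

## Pull total_mapped off a coverage table, falling back to the column sum.
coverage_total <- function(coverage, column = "count") {
  tm <- attr(coverage, "total_mapped", exact = TRUE)
  if (is.null(tm) || column != "count") sum(coverage[[column]]) else tm
}

## Write a TSV the way the rest of the package expects (plain, headered).
#' @export
write_g4cnv_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
read_g4cnv_tsv <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}

#' Read/write interval tables as BED
#'
#' Minimal 3-6 column BED support: chrom, start, end, optional name, score,
#' strand. Coordinates stay 0-based half-open on both sides of the trip.
#'
#' @param x Interval tibble (for writing).
#' @param path File path.
#' @return `read_bed()` returns an interval tibble.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score", "strand")[seq_len(ncol(df))]
  as_intervals(as_tibble(df), what = path)
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  utils::write.table(x[, keep], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
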