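#' Build a genome-wide sliding-window grid
#'
#' Windows of `window_bp` advancing by `step_bp` (defaults 200/100, i.e.
#' half-overlapping) are laid over each chromosome starting at 0. Only
#' full-length windows are emitted; a trailing stub shorter than `window_bp`
#' is dropped rather than truncated so that per-window GC and counts stay
#' comparable across the grid. A chromosome shorter than one window
#' contributes no windows (with a warning).
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param window_bp,step_bp Window size and step in bp; `window_bp >= step_bp >= 1`.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), sorted by
#'   (chrom, start).
#' @examples
#' make_windows(c(chrI = 1000))        # 9 windows, starts 0..800
#' @export
make_windows <- function(chrom_sizes, window_bp = 200, step_bp = 100) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    abort("chrom_sizes must be a named vector")
  }
  if (step_bp < 1 || window_bp < step_bp) {
    abort("need window_bp >= step_bp >= 1")
  }
  short <- chrom_sizes < window_bp
  if (any(short)) {
    warn(sprintf("chromosome(s) shorter than one window, no windows emitted: %s",
                 paste(names(chrom_sizes)[short], collapse = ", ")))
  }
  pieces <- lapply(names(chrom_sizes)[!short], function(chr) {
    starts <- seq(0, chrom_sizes[[chr]] - window_bp, by = step_bp)
    tibble(chrom = chr, start = starts, end = starts + window_bp)
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0L) return(tibble(chrom = character(), start = numeric(),
                                     end = numeric()))
  arrange(out, .data$chrom, .data$start)
}

#' Per-window GC fraction
#'
#' GC is computed as (#G + #C) / (#A + #C + #G + #T) inside each window;
#' ambiguous bases (N etc.) are excluded from both numerator and denominator.
#' A window made entirely of ambiguous bases gets `NA` and is excluded from
#' GC-dependent steps downstream.
#'
#' @param sequence Named character vector of chromosome sequences or a
#'   `Biostrings::DNAStringSet`.
#' @param windows Window grid from [make_windows()].
#' @return `windows` with a `gc` column appended.
#' @export
window_gc <- function(sequence, windows) {
  seqs <- as_string_set(sequence)
  windows <- as_intervals(windows, "windows")
  missing_chr <- setdiff(unique(windows$chrom), names(seqs))
  if (length(missing_chr)) {
    abort(sprintf("sequence missing for chromosome(s): %s",
                  paste(missing_chr, collapse = ", ")))
  }
  gc <- rep(NA_real_, nrow(windows))
  for (chr in unique(windows$chrom)) {
    idx <- which(windows$chrom == chr)
    if (max(windows$end[idx]) > Biostrings::width(seqs[chr])) {
      abort(sprintf("windows exceed the length of %s", chr))
    }
    v <- Biostrings::Views(seqs[[chr]], start = windows$start[idx] + 1L,
                           end = windows$end[idx])
    freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    gc[idx] <- ifelse(acgt == 0, NA_real_,
                      (freq[, "G"] + freq[, "C"]) / acgt)
  }
  mutate(windows, gc = gc)
}

#' Per-window read counts
#'
#' A read increments every window its aligned span overlaps by at least 1 bp
#' (at 200/100 windows, at most two). The library total is tracked
#' independently of the per-window sums because overlapping windows count a
#' read up to twice.
#'
#' Input can be (i) a tibble of aligned reads with `chrom`, `start`, `end`
#' (0-based half-open), (ii) a path to a BAM file (unmapped, secondary and
#' duplicate-marked records are skipped by default), or (iii) a per-base
#' depth track: a tibble with `chrom`, `start`, `end`, `depth` (bedGraph
#' style), in which case a window's value is the summed per-base depth over
#' the window divided by `read_length`, rounded to an integer.
#'
#' @param x Reads tibble, BAM path, or depth tibble (see Details).
#' @param windows Window grid from [make_windows()].
#' @param mode `"auto"`, `"reads"` or `"depth"`.
#' @param read_length Divisor for depth mode (bp).
#' @param sample_id Sample label carried in the result.
#' @param drop_flags For BAM input, the flags skipped (unmapped, secondary,
#'   duplicate); pass e.g. `c("unmapped")` to relax.
#' @return Coverage tibble: `windows` plus a `count` column, with attributes
#'   `total_mapped` and `sample_id`.
#' @export
window_counts <- function(x, windows, mode = c("auto", "reads", "depth"),
                          read_length = 100, sample_id = "sample",
                          drop_flags = c("unmapped", "secondary", "duplicate")) {
  mode <- match.arg(mode)
  windows <- as_intervals(windows, "windows")
  if (is.character(x) && length(x) == 1L) {
    x <- read_bam_reads(x, drop_flags)
    mode <- "reads"
  }
  x <- as_tibble(x)
  if (mode == "auto") mode <- if ("depth" %in% names(x)) "depth" else "reads"

  bad <- setdiff(unique(x$chrom), unique(windows$chrom))
  if (length(bad) && nrow(x)) {
    abort(sprintf("input contains chromosome(s) absent from the window grid: %s",
                  paste(bad, collapse = ", ")))
  }
  wgr <- intervals_to_gr(windows)
  if (mode == "reads") {
    if (nrow(x) == 0L) {
      counts <- integer(nrow(windows))
      total <- 0L
    } else {
      rgr <- intervals_to_gr(as_intervals(x, "reads"))
      counts <- GenomicRanges::countOverlaps(wgr, rgr, minoverlap = 1L)
      total <- nrow(x)
    }
  } else {
    if (!"depth" %in% names(x)) abort("depth mode needs a depth column")
    counts <- numeric(nrow(windows))
    for (chr in unique(windows$chrom)) {
      widx <- which(windows$chrom == chr)
      xc <- x[x$chrom == chr, , drop = FALSE]
      len <- max(windows$end[widx], if (nrow(xc)) max(xc$end) else 0)
      cov <- S4Vectors::Rle(0, len)
      if (nrow(xc)) {
        ir <- IRanges::IRanges(start = xc$start + 1L, end = xc$end)
        cov <- cov + IRanges::coverage(ir, weight = xc$depth, width = len)
      }
      v <- IRanges::Views(cov, start = windows$start[widx] + 1L,
                          end = windows$end[widx])
      counts[widx] <- round(IRanges::viewSums(v) / read_length)
    }
    total <- round(sum(x$depth * (x$end - x$start)) / read_length)
  }
  out <- mutate(windows, count = as.numeric(counts))
  attr(out, "total_mapped") <- as.numeric(total)
  attr(out, "sample_id") <- sample_id
  out
}

read_bam_reads <- function(path, drop_flags) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("BAM input needs the Rsamtools package")
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = if ("unmapped" %in% drop_flags) FALSE else NA,
    isSecondaryAlignment = if ("secondary" %in% drop_flags) FALSE else NA,
    isDuplicate = if ("duplicate" %in% drop_flags) FALSE else NA
  )
  p <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos", "qwidth"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  tibble(chrom = as.character(b$rname[keep]),
         start = b$pos[keep] - 1,
         end = b$pos[keep] - 1 + b$qwidth[keep])
}
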