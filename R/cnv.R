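#' Fit a GC-bias correction model
#'
#' Robust linear regression (M-estimation with Huber weights, tuning
#' constant 1.345, iterated to relative coefficient change < 1e-8 or 50
#' iterations; `MASS::rlm`) of per-window count on GC fraction. The
#' multiplicative correction factor for window w is
#' (mean fitted value over all windows) / (fitted value at gc(w)), floored
#' at 0.1 and capped at 10. If the linear fit predicts a non-positive count
#' at any observed GC, the model falls back to a log-scale fit (with a
#' warning), whose fitted values are positive by construction.
#'
#' @param coverage Coverage tibble with `gc` and `count` columns (at least
#'   100 windows with defined GC; counts not all zero).
#' @param gc_bin_width Width of the GC bins in the reported scaling table.
#' @param exclude_chroms Chromosomes excluded from the fit (typically the
#'   mitochondrial chromosome, whose copy number is far from the nuclear
#'   baseline); the fitted factors still apply genome-wide.
#' @return A `gc_model` object with elements `coefficients`, `scale`
#'   (log-scale flag), `factor_fun` (gc -> multiplicative factor),
#'   `scaling` (per-GC-bin factor tibble), `sample_id`.
#' @export
fit_gc_model <- function(coverage, gc_bin_width = 0.02,
                         exclude_chroms = NULL) {
  ok <- !is.na(coverage$gc)
  if (!is.null(exclude_chroms)) ok <- ok & !coverage$chrom %in% exclude_chroms
  if (sum(ok) < 100) abort("need >= 100 windows with defined GC")
  if (all(coverage$count[ok] == 0)) abort("all counts are zero")
  dat <- data.frame(count = coverage$count[ok], gc = coverage$gc[ok])
  if (stats::var(dat$count) == 0) {
    ## constant counts: the robust fit is degenerate but exact
    fit <- NULL
    co <- c("(Intercept)" = dat$count[1], gc = 0)
  } else {
    fit <- MASS::rlm(count ~ gc, data = dat, psi = MASS::psi.huber,
                     k = 1.345, maxit = 50, acc = 1e-8)
    co <- stats::coef(fit)
  }
  log_scale <- FALSE
  pred <- function(gc) co[[1]] + co[[2]] * gc
  if (any(pred(dat$gc) <= 0)) {
    warn("linear GC fit non-positive at observed GC; falling back to log-scale fit")
    lfit <- MASS::rlm(log(count + 0.5) ~ gc, data = dat,
                      psi = MASS::psi.huber, k = 1.345, maxit = 50,
                      acc = 1e-8)
    lco <- stats::coef(lfit)
    pred <- function(gc) exp(lco[[1]] + lco[[2]] * gc)
    co <- lco
    log_scale <- TRUE
    fit <- lfit
  }
  mean_fit <- mean(pred(dat$gc))
  factor_fun <- function(gc) {
    f <- mean_fit / pred(gc)
    f[!is.finite(f)] <- 1
    pmin(10, pmax(0.1, f))
  }
  mids <- seq(gc_bin_width / 2, 1 - gc_bin_width / 2, by = gc_bin_width)
  structure(list(coefficients = co, log_scale = log_scale,
                 factor_fun = factor_fun, mean_fitted = mean_fit,
                 scaling = tibble(gc_mid = mids, factor = factor_fun(mids)),
                 slope = co[[2]], rlm_fit = fit,
                 sample_id = attr(coverage, "sample_id", exact = TRUE) %||%
                   "sample"),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat("GC model (", if (x$log_scale) "log scale" else "linear",
      "): slope = ", format(x$slope, digits = 4),
      ", factors in [", format(min(x$scaling$factor), digits = 3), ", ",
      format(max(x$scaling$factor), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' @export
tidy.gc_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.gc_model <- function(x, ...) {
  tibble(slope = x$slope, log_scale = x$log_scale,
         mean_fitted = x$mean_fitted,
         factor_min = min(x$scaling$factor),
         factor_max = max(x$scaling$factor))
}

#' Apply a GC model to a coverage table
#'
#' Multiplies each raw count by the model's correction factor at the
#' window's GC; raw counts are preserved in `count` and the corrected value
#' is added as `count_norm`. Totals are recomputed.
#'
#' @param coverage Coverage tibble (same window grid the model was fit on).
#' @param model A [fit_gc_model()] result, or `NULL` for the identity.
#' @return Coverage tibble with `count_norm`, attribute
#'   `total_mapped_norm`.
#' @export
normalize_coverage <- function(coverage, model) {
  f <- if (is.null(model)) rep(1, nrow(coverage)) else
    model$factor_fun(coverage$gc)
  f[is.na(f)] <- 1
  out <- mutate(coverage, count_norm = .data$count * f)
  attr(out, "total_mapped") <- attr(coverage, "total_mapped", exact = TRUE)
  attr(out, "sample_id") <- attr(coverage, "sample_id", exact = TRUE)
  attr(out, "total_mapped_norm") <- sum(out$count_norm, na.rm = TRUE)
  out
}

#' Per-window chi-squared tests between a control and a mutant sample
#'
#' For each window w a 2x2 Pearson chi-squared homogeneity test (1 df, no
#' continuity correction) is computed on
#' \code{[[wt_w, wt_total - wt_w], [mut_w, mut_total - mut_w]]}, i.e. the
#' window against the rest of each library. Windows where both samples have
#' zero (and windows with undefined GC when normalized counts are used) are
#' excluded from testing. Benjamini-Hochberg adjustment is applied across
#' all tested windows of this sample pair; a window is significant when its
#' adjusted value falls below `fdr_cutoff`.
#'
#' @param wt,mut Coverage tibbles on the identical window grid (normalized,
#'   i.e. carrying `count_norm`, unless `use_normalized = FALSE`).
#' @param fdr_cutoff FDR threshold (default 0.05).
#' @param use_normalized Use `count_norm` (default) or raw `count`.
#' @return Tibble with one row per tested window: coordinates, `wt_count`,
#'   `mut_count`, `ratio` (mutant/control library-scaled coverage ratio),
#'   `statistic`, `p`, `q`, `significant`, `direction`.
#' @export
test_windows <- function(wt, mut, fdr_cutoff = 0.05, use_normalized = TRUE) {
  if (nrow(wt) != nrow(mut) ||
      !all(wt$chrom == mut$chrom & wt$start == mut$start)) {
    abort("wt and mut must share one window grid")
  }
  col <- if (use_normalized) "count_norm" else "count"
  if (!col %in% names(wt) || !col %in% names(mut)) {
    abort(sprintf("column %s missing; run normalize_coverage() first or set use_normalized = FALSE", col))
  }
  a <- as.numeric(wt[[col]]); c_ <- as.numeric(mut[[col]])
  keep <- (a + c_) > 0 & !is.na(a + c_)
  if (use_normalized && "gc" %in% names(wt)) keep <- keep & !is.na(wt$gc)
  Tw <- sum(a[keep]); Tm <- sum(c_[keep])
  if (Tw <= 0 || Tm <= 0) abort("library totals must be positive")
  a <- a[keep]; c_ <- c_[keep]
  b <- Tw - a; d <- Tm - c_
  N <- Tw + Tm
  stat <- N * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  ratio <- (c_ / Tm) / (a / Tw)
  tibble(chrom = wt$chrom[keep], start = wt$start[keep], end = wt$end[keep],
         wt_count = a, mut_count = c_, ratio = ratio,
         statistic = stat, p = p, q = q,
         significant = q < fdr_cutoff,
         direction = ifelse(ratio >= 1, "gain", "loss"))
}

#' Merge significant windows into CNV calls
#'
#' Significant windows of the same direction whose spans overlap or adjoin
#' are merged into candidate intervals; an interval is kept as a bona fide
#' CNV only when its span strictly exceeds `min_span_bp` (default 500 bp)
#' and it is supported by at least `min_windows` (default 3) significant
#' windows. A gain run is never merged with an adjacent loss run.
#'
#' @param tests Output of [test_windows()].
#' @param min_span_bp Strict minimum span in bp.
#' @param min_windows Minimum supporting significant windows.
#' @return Tibble of calls: `chrom`, `start`, `end`, `direction`,
#'   `n_windows`, `mean_ratio`, `min_q`.
#' @export
merge_calls <- function(tests, min_span_bp = 500, min_windows = 3) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  direction = character(), n_windows = integer(),
                  mean_ratio = numeric(), min_q = numeric())
  sig <- filter(tests, .data$significant)
  if (nrow(sig) == 0L) return(empty)
  out <- list()
  for (dir in unique(sig$direction)) {
    s <- sig[sig$direction == dir, , drop = FALSE]
    gr <- intervals_to_gr(s)
    red <- GenomicRanges::reduce(gr)   # merges overlapping and adjoining
    hits <- GenomicRanges::findOverlaps(gr, red)
    grp <- S4Vectors::subjectHits(hits)
    merged <- gr_to_intervals(red)
    agg <- tibble(grp = grp, ratio = s$ratio[S4Vectors::queryHits(hits)],
                  q = s$q[S4Vectors::queryHits(hits)])
    agg <- summarise(group_by(agg, .data$grp),
                     n_windows = dplyr::n(),
                     mean_ratio = mean(.data$ratio),
                     min_q = min(.data$q), .groups = "drop")
    merged$direction <- dir
    merged <- bind_cols(merged, agg[match(seq_len(nrow(merged)), agg$grp),
                                    c("n_windows", "mean_ratio", "min_q")])
    out[[dir]] <- merged
  }
  calls <- bind_rows(out)
  calls <- filter(calls, (.data$end - .data$start) > min_span_bp,
                  .data$n_windows >= min_windows)
  arrange(calls[, names(empty)], .data$chrom, .data$start)
}

#' Call CNVs against a control in one step
#'
#' Convenience wrapper: GC-normalize both samples, test windows, merge.
#'
#' @inheritParams test_windows
#' @inheritParams merge_calls
#' @param gc_normalize Fit and apply per-sample GC models first.
#' @param exclude_chroms Chromosomes excluded from the GC fit and from CNV
#'   testing (typically the mitochondrial chromosome, whose copy number is
#'   analyzed separately with [mtdna_copy_number()]).
#' @return [merge_calls()] tibble.
#' @export
call_cnvs <- function(wt, mut, fdr_cutoff = 0.05, min_span_bp = 500,
                      min_windows = 3, gc_normalize = TRUE,
                      exclude_chroms = NULL) {
  if (gc_normalize) {
    wt <- normalize_coverage(wt, fit_gc_model(wt, exclude_chroms = exclude_chroms))
    mut <- normalize_coverage(mut, fit_gc_model(mut, exclude_chroms = exclude_chroms))
  }
  if (!is.null(exclude_chroms)) {
    keep <- !wt$chrom %in% exclude_chroms
    wt <- wt[keep, , drop = FALSE]
    mut <- mut[keep, , drop = FALSE]
  }
  tests <- test_windows(wt, mut, fdr_cutoff, use_normalized = gc_normalize)
  merge_calls(tests, min_span_bp, min_windows)
}

#' Per-chromosome coverage ratios and whole-chromosome duplication flags
#'
#' Each sample's window coverage is rescaled by its genome-wide median, then
#' the per-chromosome ratio median(mut)/median(wt) is computed; a
#' chromosome is flagged duplicated when the ratio reaches `gain_threshold`
#' (1.75 by default: midway between 1 and 2 on a haploid baseline, with
#' margin for noise). Chromosomes with fewer than 10 windows report a ratio
#' but a suppressed (NA) flag, with a warning.
#'
#' @inheritParams test_windows
#' @param gain_threshold Duplication flag threshold on the rescaled ratio.
#' @return Tibble: `chrom`, `n_windows`, `ratio`, `duplicated`.
#' @export
chromosome_ploidy <- function(wt, mut, gain_threshold = 1.75,
                              use_normalized = TRUE) {
  col <- if (use_normalized && "count_norm" %in% names(wt)) "count_norm"
         else "count"
  if (nrow(wt) != nrow(mut) || !all(wt$chrom == mut$chrom)) {
    abort("wt and mut must share one window grid")
  }
  wtc <- wt[[col]] / stats::median(wt[[col]], na.rm = TRUE)
  mutc <- mut[[col]] / stats::median(mut[[col]], na.rm = TRUE)
  d <- tibble(chrom = wt$chrom, wtc = wtc, mutc = mutc)
  out <- summarise(group_by(d, .data$chrom),
                   n_windows = dplyr::n(),
                   ratio = stats::median(.data$mutc, na.rm = TRUE) /
                     stats::median(.data$wtc, na.rm = TRUE),
                   .groups = "drop")
  out <- mutate(out, duplicated = .data$ratio >= gain_threshold)
  few <- out$n_windows < 10
  if (any(few)) {
    warn(sprintf("flag suppressed for chromosome(s) with < 10 windows: %s",
                 paste(out$chrom[few], collapse = ", ")))
    out$duplicated[few] <- NA
  }
  out
}

#' Aggregate window coverage into per-feature counts
#'
#' Sums window counts over each feature weighted by the window/feature
#' overlap fraction and divides by the window/step overlap factor, so that
#' with half-overlapping windows a read is not double-counted.
#'
#' @param coverage Coverage tibble.
#' @param features Interval tibble with a `name` (or `gene`) column.
#' @param column Count column to aggregate.
#' @return Tibble: `name`, `chrom`, `start`, `end`, `length`, `count`.
#' @export
feature_counts <- function(coverage, features, column = "count") {
  features <- as_tibble(features)
  if (!"name" %in% names(features)) {
    features$name <- if ("gene" %in% names(features)) features$gene else
      sprintf("feature%03d", seq_len(nrow(features)))
  }
  feats <- as_intervals(features, "features")
  wgr <- intervals_to_gr(coverage)
  fgr <- intervals_to_gr(feats)
  window_bp <- stats::median(coverage$end - coverage$start)
  starts <- sort(unique(coverage$start))
  step_bp <- if (length(starts) > 1) min(diff(starts)) else window_bp
  overlap_factor <- window_bp / step_bp
  hits <- GenomicRanges::findOverlaps(wgr, fgr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  frac <- GenomicRanges::width(GenomicRanges::pintersect(wgr[qh], fgr[sh])) /
    window_bp
  agg <- tibble(f = sh, x = coverage[[column]][qh] * frac)
  agg <- summarise(group_by(agg, .data$f), count = sum(.data$x),
                   .groups = "drop")
  out <- mutate(feats, length = .data$end - .data$start, count = 0)
  out$count[agg$f] <- agg$count / overlap_factor
  select(out, "name", "chrom", "start", "end", "length", "count")
}

#' Mitochondrial DNA copy number from RPKM ratios
#'
#' RPKM = count / (length_kb x total_mapped_millions). The copy number is
#' the mtDNA RPKM divided by the mean RPKM of single-copy nuclear genes, so
#' that more mitochondria give a larger number (set `invert = TRUE` for the
#' reciprocal). Optionally quantile-normalizes the per-feature RPKM vectors
#' across samples first (requires limma).
#'
#' @param counts Per-feature count tibble(s) as from [feature_counts()],
#'   with a logical `is_mt` column or `mt_names` given; one tibble per
#'   sample (named list for multiple samples).
#' @param total_mapped Total mapped reads per sample (vector aligned with
#'   `counts` when a list).
#' @param mt_names Feature names treated as mitochondrial.
#' @param quantile_normalize Quantile-normalize RPKM across samples first.
#' @param invert Report nuclear/mt instead of mt/nuclear.
#' @param control Sample name used as denominator for `relative_copy_number`.
#' @return Tibble: `sample_id`, `mt_rpkm`, `nuclear_rpkm`, `copy_number`,
#'   and `relative_copy_number` when `control` is given.
#' @export
mtdna_copy_number <- function(counts, total_mapped, mt_names = "chrM",
                              quantile_normalize = FALSE, invert = FALSE,
                              control = NULL) {
  if (is.data.frame(counts)) counts <- list(sample = counts)
  if (is.null(names(counts))) names(counts) <- paste0("sample", seq_along(counts))
  if (length(total_mapped) != length(counts)) {
    abort("need one total_mapped per sample")
  }
  if (any(total_mapped <= 0)) abort("total mapped reads must be positive")
  rpkm <- purrr::imap(counts, function(x, nm) {
    i <- match(nm, names(counts))
    x$rpkm <- x$count / ((x$length / 1000) * (total_mapped[i] / 1e6))
    x
  })
  if (quantile_normalize) {
    if (!requireNamespace("limma", quietly = TRUE)) {
      abort("quantile_normalize needs the limma package")
    }
    mat <- do.call(cbind, lapply(rpkm, function(x) x$rpkm))
    mat <- limma::normalizeQuantiles(mat)
    for (i in seq_along(rpkm)) rpkm[[i]]$rpkm <- mat[, i]
  }
  rows <- purrr::imap(rpkm, function(x, nm) {
    is_mt <- if ("is_mt" %in% names(x)) x$is_mt else
      x$name %in% mt_names | x$chrom %in% mt_names
    if (!any(is_mt)) abort("no mitochondrial feature found")
    if (all(is_mt)) abort("no single-copy nuclear features found")
    mt <- mean(x$rpkm[is_mt])
    nuc <- mean(x$rpkm[!is_mt])
    cn <- if (invert) nuc / mt else mt / nuc
    tibble(sample_id = nm, mt_rpkm = mt, nuclear_rpkm = nuc,
           copy_number = cn)
  })
  out <- bind_rows(rows)
  if (!is.null(control)) {
    if (!control %in% out$sample_id) abort("control sample not found")
    ref <- out$copy_number[out$sample_id == control]
    out$relative_copy_number <- out$copy_number / ref
  }
  out
}
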