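#' @import ggplot2
NULL

#' Plot windowed coverage with optional CNV calls
#'
#' @param coverage Coverage tibble.
#' @param calls Optional [merge_calls()] tibble highlighted as rectangles.
#' @param chroms Chromosomes to show (default all).
#' @param column Count column to plot.
#' @return A ggplot.
#' @export
plot_coverage <- function(coverage, calls = NULL, chroms = NULL,
                          column = "count") {
  d <- coverage
  if (!is.null(chroms)) d <- filter(d, .data$chrom %in% chroms)
  p <- ggplot(d, aes(x = (.data$start + .data$end) / 2,
                     y = .data[[column]])) +
    geom_point(size = 0.3, alpha = 0.4) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (bp)", y = "reads / window")
  if (!is.null(calls) && nrow(calls)) {
    cc <- if (!is.null(chroms)) filter(calls, .data$chrom %in% chroms) else calls
    p <- p + geom_rect(data = cc,
                       aes(xmin = .data$start, xmax = .data$end,
                           fill = .data$direction),
                       ymin = -Inf, ymax = Inf, alpha = 0.25,
                       inherit.aes = FALSE)
  }
  p
}

#' @export
autoplot.gc_model <- function(object, ...) {
  ggplot(object$scaling, aes(x = .data$gc_mid, y = .data$factor)) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = 2) +
    labs(x = "GC fraction", y = "correction factor",
         title = sprintf("GC model (%s scale)",
                         if (object$log_scale) "log" else "linear"))
}

#' @export
autoplot.tds_result <- function(object, pivot_nm = 290, ...) {
  ggplot(object, aes(x = .data$wavelength, y = .data$tds)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = 2) +
    geom_vline(xintercept = pivot_nm, linetype = 3) +
    labs(x = "wavelength (nm)", y = expression(Delta * A / A[max]))
}

#' @export
autoplot.distance_null <- function(object, ...) {
  d <- tibble(x = object$replicate_summary)
  ggplot(d, aes(x = .data$x)) +
    geom_histogram(bins = 40) +
    geom_vline(xintercept = object$observed_summary, colour = "red") +
    labs(x = "replicate summary distance (bp)", y = "replicates",
         title = sprintf("empirical p = %.3g (%d reps)", object$p,
                         object$n_reps))
}

#' @export
autoplot.kinetic_fit <- function(object, curve = NULL, ...) {
  if (is.null(curve)) {
    return(ggplot(object$steps, aes(x = .data$conc, y = .data$k_obs)) +
             geom_point() +
             geom_abline(intercept = object$koff, slope = object$kon) +
             labs(x = "concentration (nM)", y = expression(k[obs] ~ (s^-1))))
  }
  d <- augment(object, curve)
  ggplot(d, aes(x = .data$time)) +
    geom_point(aes(y = .data$sigma), size = 0.4, alpha = 0.5) +
    geom_line(aes(y = .data$.fitted), colour = "red") +
    labs(x = "time (s)", y = expression(sigma(t)))
}
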