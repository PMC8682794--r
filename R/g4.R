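#' Scan sequences for G-quadruplex motifs
#'
#' Greedy left-to-right search for at least `min_runs` G-runs of at least
#' `min_run_len` nt separated by loops of `loop_min` to `loop_max` nt.
#' Both strands are scanned (C-runs on the forward strand are G-runs on the
#' reverse); overlapping matches on one strand are merged into a single
#' motif per locus so nested matches do not inflate counts. The default
#' parameters (4 runs of G>=3, loops 1-25) match the canonical quadparser
#' definition.
#'
#' @param sequence Named character vector of sequences, a single string, or
#'   a `Biostrings::DNAStringSet` (alphabet A/C/G/T/N).
#' @param min_run_len Minimum G-run length (nt).
#' @param min_runs Minimum number of G-runs.
#' @param loop_min,loop_max Loop length bounds (nt).
#' @param strand `"both"` (default), `"+"` or `"-"`.
#' @return Tibble of motifs: `chrom`, `start`, `end` (0-based half-open,
#'   forward-strand coordinates), `strand`, `sequence` (G-rich strand),
#'   `n_runs`, `run_lengths`, `loop_lengths` (comma-separated).
#' @examples
#' scan_g4("GGGTTAGGGTTAGGGTTAGGG")
#' @export
scan_g4 <- function(sequence, min_run_len = 3, min_runs = 4,
                    loop_min = 1, loop_max = 25, strand = "both") {
  if (loop_max < loop_min) abort("loop_max must be >= loop_min")
  if (inherits(sequence, "DNAStringSet")) {
    sequence <- stats::setNames(as.character(sequence), names(sequence))
  }
  if (is.null(names(sequence))) {
    names(sequence) <- if (length(sequence) == 1L) "seq" else
      paste0("seq", seq_along(sequence))
  }
  strands <- switch(strand, both = c("+", "-"), "+" = "+", "-" = "-",
                    abort("strand must be 'both', '+' or '-'"))
  out <- list()
  for (chr in names(sequence)) {
    s <- toupper(sequence[[chr]])
    for (st in strands) {
      base <- if (st == "+") "G" else "C"
      pat <- sprintf("%s{%d,}(?:[ACGTN]{%d,%d}?%s{%d,}){%d,}",
                     base, min_run_len, loop_min, loop_max, base,
                     min_run_len, min_runs - 1)
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      ir <- IRanges::reduce(IRanges::IRanges(
        start = as.integer(m), width = attr(m, "match.length")))
      for (i in seq_along(ir)) {
        sub <- substr(s, IRanges::start(ir)[i], IRanges::end(ir)[i])
        grich <- if (st == "+") sub else revcomp(sub)
        runs <- gregexpr(sprintf("G{%d,}", min_run_len), grich)[[1]]
        rl <- attr(runs, "match.length")
        loops <- if (length(runs) > 1) {
          runs[-1] - (runs[-length(runs)] + rl[-length(rl)])
        } else integer(0)
        out[[length(out) + 1L]] <- tibble(
          chrom = chr, start = IRanges::start(ir)[i] - 1,
          end = as.numeric(IRanges::end(ir)[i]), strand = st,
          sequence = grich, n_runs = length(runs),
          run_lengths = paste(rl, collapse = ","),
          loop_lengths = paste(loops, collapse = ","))
      }
    }
  }
  if (!length(out)) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), sequence = character(),
                  n_runs = integer(), run_lengths = character(),
                  loop_lengths = character()))
  }
  arrange(bind_rows(out), .data$chrom, .data$start)
}

#' Overlaps between two interval sets
#'
#' Half-open semantics: \[s1, e1) overlaps \[s2, e2) iff s1 < e2 and
#' s2 < e1; touching intervals do not overlap.
#'
#' @param a,b Interval tibbles.
#' @return Tibble of overlapping pairs: indices into `a` and `b`,
#'   coordinates of both, and `overlap_bp`.
#' @export
intersect_intervals <- function(a, b) {
  a <- as_intervals(a, "a"); b <- as_intervals(b, "b")
  empty <- tibble(a_idx = integer(), b_idx = integer(),
                  chrom = character(), a_start = numeric(), a_end = numeric(),
                  b_start = numeric(), b_end = numeric(),
                  overlap_bp = numeric())
  if (!nrow(a) || !nrow(b)) return(empty)
  agr <- intervals_to_gr(a); bgr <- intervals_to_gr(b)
  hits <- GenomicRanges::findOverlaps(agr, bgr, minoverlap = 1L)
  if (!length(hits)) return(empty)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  tibble(a_idx = qh, b_idx = sh, chrom = a$chrom[qh],
         a_start = a$start[qh], a_end = a$end[qh],
         b_start = b$start[sh], b_end = b$end[sh],
         overlap_bp = pmin(a$end[qh], b$end[sh]) -
           pmax(a$start[qh], b$start[sh]))
}

## Exact conditional p-values for a 2x2 table with fixed margins.
## x successes out of k draws from an urn with m successes and n failures.
## Two-sided rule: sum the probabilities of all outcomes no more likely
## than the observed one (Fisher's rule, as stats::fisher.test).
exact_table_p <- function(m, n, k) {
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  d <- stats::dhyper(x, m, n, k)
  ord <- order(d)
  cs <- cumsum(d[ord])
  p_two <- numeric(length(x))
  p_two[ord] <- cs[findInterval(d[ord] * (1 + 1e-7), d[ord])]
  ## findInterval over sorted d: index of last d_j <= d_x (with tolerance)
  p_two <- pmin(1, p_two)
  p_up <- stats::phyper(x - 1, m, n, k, lower.tail = FALSE)
  tibble(x = x, p_two_sided = p_two, p_upper = p_up)
}

fisher_exact_p <- function(a, b, c, d) {
  tab <- exact_table_p(m = a + c, n = b + d, k = a + b)
  i <- match(a, tab$x)
  list(p_two_sided = tab$p_two_sided[i], p_upper = tab$p_upper[i])
}

#' Overlap enrichment of a query interval set in G4 elements
#'
#' Every universe interval (typically the genome-wide window grid) is
#' classified by whether it overlaps the query set and whether it overlaps
#' the G4 set; the resulting 2x2 table is tested with Fisher's exact test
#' (two-sided) and the one-sided hypergeometric upper tail. The odds ratio
#' uses the Haldane 0.5 correction when any cell is zero.
#'
#' @param query,g4 Interval tibbles.
#' @param universe Interval tibble covering the genome (e.g.
#'   [make_windows()] output).
#' @return An `enrichment_result`: list with `table` (2x2 matrix),
#'   `odds_ratio`, `p_fisher`, `p_hyper`.
#' @export
overlap_enrichment <- function(query, g4, universe) {
  universe <- as_intervals(universe, "universe")
  ugr <- intervals_to_gr(universe)
  q_ov <- if (nrow(query)) IRanges::overlapsAny(
    ugr, intervals_to_gr(as_intervals(query, "query"))) else
    logical(length(ugr))
  g_ov <- if (nrow(g4)) IRanges::overlapsAny(
    ugr, intervals_to_gr(as_intervals(g4, "g4"))) else logical(length(ugr))
  a <- sum(q_ov & g_ov); b <- sum(q_ov & !g_ov)
  c_ <- sum(!q_ov & g_ov); d <- sum(!q_ov & !g_ov)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(query = c("in", "out"),
                                g4 = c("in", "out")))
  degenerate <- (a + b == 0) || (c_ + d == 0) || (a + c_ == 0) || (b + d == 0)
  if (degenerate) {
    warn("degenerate 2x2 margins; p set to 1")
    ps <- list(p_two_sided = 1, p_upper = 1)
  } else {
    ps <- fisher_exact_p(a, b, c_, d)
  }
  or <- if (any(c(a, b, c_, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else (a * d) / (b * c_)
  structure(list(table = tab, odds_ratio = or,
                 p_fisher = ps$p_two_sided, p_hyper = ps$p_upper),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Overlap enrichment (universe units:", sum(x$table), ")\n")
  print(x$table)
  cat(sprintf("odds ratio %.3g; Fisher two-sided p = %.3g; hypergeometric upper p = %.3g\n",
              x$odds_ratio, x$p_fisher, x$p_hyper))
  invisible(x)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(in_query_in_g4 = x$table[1, 1], in_query_out_g4 = x$table[1, 2],
         out_query_in_g4 = x$table[2, 1], out_query_out_g4 = x$table[2, 2],
         odds_ratio = x$odds_ratio, p_fisher = x$p_fisher,
         p_hyper = x$p_hyper)
}

#' Distance from each query interval to the nearest G4 element
#'
#' Edge-to-edge gap in bp to the nearest G4 on the same chromosome; 0 when
#' overlapping (or bookended). Query intervals on chromosomes without any
#' G4 are excluded with a warning.
#'
#' @param query,g4 Interval tibbles (`g4` non-empty).
#' @return `query` rows that have a same-chromosome G4, with a `distance`
#'   column appended.
#' @export
distance_to_nearest <- function(query, g4) {
  query <- as_intervals(query, "query")
  g4 <- as_intervals(g4, "g4")
  if (!nrow(g4)) abort("g4 set is empty")
  qgr <- intervals_to_gr(query); ggr <- intervals_to_gr(g4)
  hits <- GenomicRanges::distanceToNearest(qgr, ggr)
  covered <- S4Vectors::queryHits(hits)
  if (length(covered) < nrow(query)) {
    warn(sprintf("%d query interval(s) on chromosomes without G4 excluded",
                 nrow(query) - length(covered)))
  }
  out <- query[covered, , drop = FALSE]
  out$distance <- as.numeric(S4Vectors::mcols(hits)$distance)
  out
}

## Vectorized nearest-gap kernel used inside the resampling null: for query
## intervals on ONE chromosome against sorted g4 intervals on it.
nearest_gap_1chrom <- function(qs, qe, gs, ge) {
  o <- order(gs)
  gs <- gs[o]; ge <- ge[o]
  ge_cm <- cummax(ge)
  j <- findInterval(qs, gs)                 # last g4 with gs <= qs
  left <- ifelse(j >= 1, qs - ge_cm[pmax(j, 1)], Inf)
  right <- ifelse(j < length(gs), gs[pmin(j + 1, length(gs))] - qe, Inf)
  pmax(0, pmin(left, right))
}

nearest_gap <- function(query, g4) {
  d <- rep(NA_real_, nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    gi <- which(g4$chrom == chr)
    if (!length(gi)) next
    d[qi] <- nearest_gap_1chrom(query$start[qi], query$end[qi],
                                g4$start[gi], g4$end[gi])
  }
  d
}

#' Matched resampling null for distances to G4 elements
#'
#' Each replicate draws `nrow(query)` intervals, each of the same length as
#' one observed query interval (matched one-to-one), placed uniformly at
#' random genome-wide: the chromosome is chosen with probability
#' proportional to the number of placeable start positions for that length,
#' then the start uniformly among them. The replicate's distance-to-nearest
#' distribution is summarised (`mean` by default) and the empirical
#' lower-tail p-value -- are the observed queries closer to G4 than
#' expected? -- uses the +1/(n+1) rule.
#'
#' @param query,g4 Interval tibbles.
#' @param chrom_sizes Named chromosome lengths (bp).
#' @param n_reps Number of resampling replicates (default 1000).
#' @param summary Summary statistic applied to each distance set
#'   (`mean`, default, or e.g. `median`).
#' @param seed Integer seed.
#' @return A `distance_null`: list with `observed` (distances),
#'   `observed_summary`, `replicate_summary` (length `n_reps`), `p`,
#'   `n_reps`, `seed`.
#' @export
resample_null <- function(query, g4, chrom_sizes, n_reps = 1000,
                          summary = mean, seed) {
  if (missing(seed)) abort("resample_null needs an explicit seed")
  if (n_reps < 1) abort("n_reps must be >= 1")
  query <- as_intervals(query, "query")
  g4 <- as_intervals(g4, "g4")
  lens <- query$end - query$start
  L <- as.numeric(chrom_sizes)
  chroms <- names(chrom_sizes)
  obs_d <- nearest_gap(query, g4)
  if (anyNA(obs_d)) {
    warn(sprintf("%d query interval(s) on chromosomes without G4 excluded",
                 sum(is.na(obs_d))))
  }
  obs_sum <- summary(obs_d[!is.na(obs_d)])
  rep_mat <- matrix(NA_real_, nrow = length(lens), ncol = n_reps)
  eval_with_seed(seed, {
    for (i in seq_along(lens)) {
      placeable <- pmax(0, L - lens[i] + 1)
      if (sum(placeable) == 0) abort("query interval longer than every chromosome")
      ci <- sample.int(length(L), n_reps, replace = TRUE, prob = placeable)
      starts <- floor(stats::runif(n_reps) * placeable[ci])
      placed <- tibble(chrom = chroms[ci], start = starts,
                       end = starts + lens[i], rep = seq_len(n_reps))
      rep_mat[i, ] <- nearest_gap(placed, g4)
    }
  })
  rep_sum <- apply(rep_mat, 2, function(d) summary(d[!is.na(d)]))
  ok <- is.finite(rep_sum)
  if (!all(ok)) {
    warn(sprintf("%d replicate(s) had no interval on a G4-bearing chromosome and were dropped",
                 sum(!ok)))
  }
  p <- (1 + sum(rep_sum[ok] <= obs_sum)) / (sum(ok) + 1)
  structure(list(observed = obs_d[!is.na(obs_d)], observed_summary = obs_sum,
                 replicate_summary = rep_sum, p = p, n_reps = n_reps,
                 seed = seed),
            class = "distance_null")
}

#' @export
print.distance_null <- function(x, ...) {
  cat(sprintf("Resampling null (%d reps): observed summary %.1f bp, empirical p = %.4g\n",
              x$n_reps, x$observed_summary, x$p))
  invisible(x)
}

#' @export
glance.distance_null <- function(x, ...) {
  tibble(observed_summary = x$observed_summary,
         replicate_mean = mean(x$replicate_summary),
         n_reps = x$n_reps, p = x$p)
}
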