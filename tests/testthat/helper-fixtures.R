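## Shared fixtures and independent oracles used across test files.

## Published G4 cassette sequences used in the GCR assay, and their mutants in
## which two internal GGG runs carry G->C substitutions that abolish G4
## formation while keeping GC content.
gcr_cassette <- "GGGTCCTCCAAGCGGTAAAACTTACATGGGATGGTGGGGTCACATGGG"
gcr_cassette_mut <- sub("CATGGGATG", "CATGCGATG",
                        sub("GTGGGGTCA", "GTGCGGTCA", gcr_cassette))
chr8_g4 <- "GGGTTTTGCTATAATAGGGATGCCATAAGTGAGGGCAGGG"
chr8_g4_mut <- sub("TAGGGAT", "TAGCGAT", sub("GAGGGCA", "GAGCGCA", chr8_g4))

## Brute-force read x window overlap counter (the counting oracle).
brute_force_counts <- function(reads, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(reads$chrom == windows$chrom[i] &
          reads$start < windows$end[i] &
          windows$start[i] < reads$end)
  }, numeric(1))
}

## Textbook Benjamini-Hochberg step-up, written independently of p.adjust:
## q_(i) = min_{j >= i} ( n * p_(j) / j ), in the original order.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

## From-scratch hypergeometric enumeration oracle via log-factorials:
## probabilities of every table with the given margins, two-sided p by
## Fisher's rule, upper tail by summation.
enum_oracle <- function(m, n, k) {
  lo <- max(0L, k - n); hi <- min(k, m)
  x <- lo:hi
  lp <- lgamma(m + 1) - lgamma(x + 1) - lgamma(m - x + 1) +
    lgamma(n + 1) - lgamma(k - x + 1) - lgamma(n - k + x + 1) -
    (lgamma(m + n + 1) - lgamma(k + 1) - lgamma(m + n - k + 1))
  d <- exp(lp)
  le <- outer(d, d * (1 + 1e-7), "<=")   # le[j, i]: table j no more likely than i
  p2 <- pmin(1, colSums(le * d))
  pu <- rev(cumsum(rev(d)))
  list(x = x, p2 = p2, pu = pu)
}

## 50% reciprocal-overlap matching of calls against truth.
reciprocal_match <- function(calls, truth, frac = 0.5) {
  if (nrow(calls) == 0) return(list(recall = 0, precision = NA_real_))
  ov <- intersect_intervals(calls, truth)
  ov$f1 <- ov$overlap_bp / (ov$a_end - ov$a_start)
  ov$f2 <- ov$overlap_bp / (ov$b_end - ov$b_start)
  ov <- ov[ov$f1 >= frac & ov$f2 >= frac, , drop = FALSE]
  list(recall = length(unique(ov$b_idx)) / nrow(truth),
       precision = length(unique(ov$a_idx)) / nrow(calls))
}

## Uniform random interval placement matching resample_null's rule
## (chromosome ~ placeable positions, start uniform).
place_random_intervals <- function(lens, chrom_sizes, seed) {
  set.seed(seed)
  L <- as.numeric(chrom_sizes); chroms <- names(chrom_sizes)
  rows <- lapply(seq_along(lens), function(i) {
    placeable <- pmax(0, L - lens[i] + 1)
    ci <- sample.int(length(L), 1, prob = placeable)
    s <- floor(stats::runif(1) * placeable[ci])
    data.frame(chrom = chroms[ci], start = s, end = s + lens[i])
  })
  tibble::as_tibble(do.call(rbind, rows))
}
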