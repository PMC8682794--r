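test_that("scanner finds the published GCR-assay cassettes, not their mutants", {
  expect_gte(nrow(scan_g4(gcr_cassette)), 1)
  expect_gte(nrow(scan_g4(chr8_g4)), 1)
  expect_equal(nrow(scan_g4(gcr_cassette_mut)), 0)
  expect_equal(nrow(scan_g4(chr8_g4_mut)), 0)
  expect_equal(nrow(scan_g4(strrep("A", 500))), 0)
})

test_that("scanner respects run, loop and strand rules", {
  tel <- "GGGTTAGGGTTAGGGTTAGGG"
  hit <- scan_g4(tel)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$n_runs, 4L)
  expect_equal(hit$run_lengths, "3,3,3,3")
  expect_equal(hit$loop_lengths, "3,3,3")
  expect_equal(hit$start, 0)
  expect_equal(hit$end, nchar(tel))
  ## reverse strand: C-runs on the forward strand
  rc <- scan_g4(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tel))))
  expect_equal(nrow(rc), 1)
  expect_equal(rc$strand, "-")
  expect_equal(rc$sequence, tel)
  ## loops above loop_max break the motif
  spread <- paste0("GGG", strrep("T", 26), "GGGTTGGGTTGGG")
  expect_equal(nrow(scan_g4(spread)), 0)
  expect_equal(nrow(scan_g4(spread, loop_max = 30)), 1)
  ## three runs are not enough at min_runs = 4
  expect_equal(nrow(scan_g4("GGGTTGGGTTGGG")), 0)
  expect_equal(nrow(scan_g4("GGGTTGGGTTGGG", min_runs = 3)), 1)
  expect_error(scan_g4("GGG", loop_min = 5, loop_max = 2), "loop_max")
})

test_that("interval intersection matches half-open semantics and brute force", {
  a <- tibble::tibble(chrom = "c", start = 0, end = 100)
  b <- tibble::tibble(chrom = "c", start = 100, end = 200)
  expect_equal(nrow(intersect_intervals(a, b)), 0)   # touching, not overlapping
  ab <- intersect_intervals(tibble::tibble(chrom = "c", start = 0, end = 150),
                            b)
  expect_equal(nrow(ab), 1)
  expect_equal(ab$overlap_bp, 50)

  set.seed(71)
  mk <- function(n) {
    s <- sample(0:5000, n, replace = TRUE)
    tibble::tibble(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                   start = s, end = s + sample(10:400, n, replace = TRUE))
  }
  A <- mk(300); B <- mk(300)
  got <- intersect_intervals(A, B)
  As <- as_intervals(A); Bs <- as_intervals(B)
  brute <- list()
  for (i in seq_len(nrow(As))) for (j in seq_len(nrow(Bs))) {
    if (As$chrom[i] == Bs$chrom[j] && As$start[i] < Bs$end[j] &&
        Bs$start[j] < As$end[i]) {
      brute[[length(brute) + 1L]] <- c(i, j)
    }
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(got), nrow(brute))
  expect_setequal(paste(got$a_idx, got$b_idx),
                  paste(brute[, 1], brute[, 2]))
})

test_that("exact enrichment test matches enumeration and fisher.test", {
  ## enumeration oracle on a band of small margins
  for (m in c(3, 10, 25)) for (n in c(5, 25)) for (k in c(2, 8, 20)) {
    if (k > m + n) next
    pkg <- g4cnv:::exact_table_p(m, n, k)
    or <- enum_oracle(m, n, k)
    expect_lt(max(abs(pkg$p_two_sided - or$p2)), 1e-12)
    expect_lt(max(abs(pkg$p_upper - or$pu)), 1e-12)
  }
  ## spot-check against stats::fisher.test on random tables
  set.seed(72)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    ft <- stats::fisher.test(tab)$p.value
    pk <- g4cnv:::fisher_exact_p(tab[1, 1], tab[1, 2],
                                 tab[2, 1], tab[2, 2])$p_two_sided
    expect_equal(pk, ft, tolerance = 1e-12)
  }
})

test_that("overlap enrichment classifies universe windows", {
  uni <- make_windows(c(c1 = 100000))
  g4 <- tibble::tibble(chrom = "c1", start = c(10000, 50000),
                       end = c(10030, 50030))
  ## query exactly on the g4 windows: minimal p, capped odds ratio
  res <- overlap_enrichment(g4, g4, uni)
  expect_equal(res$table[1, 1] + res$table[1, 2], res$table[1, 1])
  expect_lt(res$p_fisher, 1e-8)
  expect_gt(res$odds_ratio, 100)
  ## independent query: p not extreme
  far <- tibble::tibble(chrom = "c1", start = 80000, end = 80030)
  res2 <- overlap_enrichment(far, g4, uni)
  expect_gt(res2$p_fisher, 0.05)
  ## degenerate margins
  expect_warning(res3 <- overlap_enrichment(uni, g4, uni), "degenerate")
  expect_equal(res3$p_fisher, 1)
})

test_that("enrichment p is calibrated on independently placed queries", {
  g <- simulate_genome(c(chrI = 120000, chrII = 100000), g4_density = 1,
                       mt_chrom = NULL, seed = 73)
  uni <- make_windows(g$chrom_sizes)
  ps <- vapply(1:100, function(s) {
    q <- place_random_intervals(rep(300, 15), g$chrom_sizes, seed = 2000 + s)
    overlap_enrichment(q, g$g4, uni)$p_hyper
  }, numeric(1))
  ## discrete conservative p: uniformity only roughly, check no inflation
  expect_gt(mean(ps > 0.05), 0.80)
  expect_gt(min(ps), 1e-4)
})

test_that("nearest distances match the definition and brute force", {
  q <- tibble::tibble(chrom = "c", start = 100, end = 200)
  g4a <- tibble::tibble(chrom = "c", start = 300, end = 350)
  expect_equal(distance_to_nearest(q, g4a)$distance, 100)
  expect_equal(distance_to_nearest(q, tibble::tibble(chrom = "c",
                                                     start = 150, end = 180))$distance, 0)
  set.seed(74)
  mk <- function(n) {
    s <- sample(0:20000, n, replace = TRUE)
    tibble::tibble(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                   start = s, end = s + sample(5:200, n, replace = TRUE))
  }
  Q <- as_intervals(mk(100)); G <- as_intervals(mk(60))
  got <- suppressWarnings(distance_to_nearest(Q, G))
  brute <- vapply(seq_len(nrow(Q)), function(i) {
    same <- G[G$chrom == Q$chrom[i], , drop = FALSE]
    if (!nrow(same)) return(NA_real_)
    min(pmax(0, pmax(same$start - Q$end[i], Q$start[i] - same$end)))
  }, numeric(1))
  expect_equal(got$distance, brute[!is.na(brute)])
  ## the fast kernel used by the resampling null agrees with the GRanges path
  expect_equal(g4cnv:::nearest_gap(Q, G), brute)
})

test_that("resampling null is deterministic, exact on planted overlaps", {
  g <- simulate_genome(c(chrI = 150000, chrII = 120000), g4_density = 1,
                       mt_chrom = NULL, seed = 75)
  q <- g$g4[seq_len(min(8, nrow(g$g4))), c("chrom", "start", "end")]
  r1 <- resample_null(q, g$g4, g$chrom_sizes, n_reps = 199, seed = 5)
  r2 <- resample_null(q, g$g4, g$chrom_sizes, n_reps = 199, seed = 5)
  expect_identical(r1$replicate_summary, r2$replicate_summary)
  expect_equal(r1$observed_summary, 0)
  expect_equal(r1$p, 1 / 200)
  r3 <- resample_null(q, g$g4, g$chrom_sizes, n_reps = 199, seed = 6)
  expect_false(identical(r1$replicate_summary, r3$replicate_summary))
})

test_that("null placement is uniform over the genome", {
  sizes <- c(c1 = 50000, c2 = 30000)
  g4 <- tibble::tibble(chrom = "c1", start = 0, end = 10)
  q <- tibble::tibble(chrom = "c1", start = 0, end = 50)
  r <- suppressWarnings(resample_null(q, g4, sizes, n_reps = 20000, seed = 7))
  ## distances from c1 placements reflect uniform starts: the mean distance
  ## of a uniform 50 bp interval to an anchor at the chromosome start is
  ## ~ (L - 50)/2; dropped c2 placements leave ~ c1-share of replicates
  keep <- is.finite(r$replicate_summary)
  expect_equal(mean(keep), 50000 / 80000, tolerance = 0.02)
  expect_equal(mean(r$replicate_summary[keep]), (50000 - 50) / 2,
               tolerance = 0.02)
})
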