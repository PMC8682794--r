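make_cov <- function(counts, gc = NULL, chrom = "chr") {
  n <- length(counts)
  out <- tibble::tibble(chrom = chrom,
                        start = seq(0, by = 100, length.out = n),
                        end = seq(200, by = 100, length.out = n),
                        gc = gc %||% rep(0.4, n),
                        count = counts)
  attr(out, "total_mapped") <- sum(counts)
  out
}

test_that("GC model is inert on constant counts and bias-free data", {
  cov <- make_cov(rep(50, 500), gc = runif(500, 0.3, 0.5))
  gm <- fit_gc_model(cov)
  expect_equal(unname(gm$slope), 0, tolerance = 1e-10)
  expect_equal(gm$scaling$factor, rep(1, nrow(gm$scaling)), tolerance = 1e-10)

  g <- simulate_genome(c(chrI = 400000), g4_density = 0, mt_chrom = NULL,
                       seed = 21)
  cov2 <- simulate_coverage(g, depth = 100, gc_bias = "identity",
                            noise = "poisson", seed = 22)
  gm2 <- fit_gc_model(cov2)
  f_obs <- gm2$factor_fun(cov2$gc)
  expect_true(all(f_obs > 0.95 & f_obs < 1.05))
  expect_error(fit_gc_model(make_cov(rep(0, 500))), "zero")
  expect_error(fit_gc_model(make_cov(rep(5, 50))), "100 windows")
})

test_that("quadratic planted bias is removed by normalization", {
  g <- simulate_genome(c(chrI = 500000, chrII = 500000), g4_density = 0,
                       mt_chrom = NULL, seed = 23)
  cov <- simulate_coverage(g, depth = 100, gc_bias = "quadratic",
                           noise = "poisson", seed = 24)
  gm <- fit_gc_model(cov)
  norm <- normalize_coverage(cov, gm)
  pre <- abs(stats::coef(MASS::rlm(count ~ gc, data = norm, maxit = 50))[2])
  post <- abs(stats::coef(MASS::rlm(count_norm ~ gc, data = norm,
                                    maxit = 50))[2])
  expect_lt(post, 0.05 * pre)
  ## raw counts preserved alongside
  expect_identical(norm$count, cov$count)
})

test_that("normalization is the identity under a null model and is linear", {
  cov <- make_cov(rpois(300, 80), gc = runif(300, 0.3, 0.5))
  idn <- normalize_coverage(cov, NULL)
  expect_equal(idn$count_norm, cov$count)
  gm <- fit_gc_model(cov)
  n1 <- normalize_coverage(cov, gm)
  gm2 <- gm
  gm2$factor_fun <- function(gc) 2 * gm$factor_fun(gc)
  n2 <- normalize_coverage(cov, gm2)
  expect_equal(n2$count_norm, 2 * n1$count_norm)
})

test_that("window chi-squared matches Pearson's formula and BH the step-up", {
  ## identical profiles: statistic 0, p 1, nothing significant
  cov <- make_cov(rpois(200, 60))
  cov$count_norm <- cov$count
  tw <- test_windows(cov, cov)
  expect_true(all(tw$statistic == 0))
  expect_true(all(tw$p == 1))
  expect_false(any(tw$significant))

  ## hand-evaluated 2x2: [[100, 9900], [200, 9800]]
  a <- 100; b <- 9900; c <- 200; d <- 9800; N <- a + b + c + d
  stat_hand <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  wt <- make_cov(c(100, 9900)); wt$count_norm <- wt$count
  mu <- make_cov(c(200, 9800)); mu$count_norm <- mu$count
  tw2 <- test_windows(wt, mu)
  expect_equal(tw2$statistic[1], stat_hand, tolerance = 1e-12)
  expect_equal(tw2$p[1],
               stats::pchisq(stat_hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  ## and against stats::chisq.test without continuity correction
  ct <- suppressWarnings(stats::chisq.test(matrix(c(a, b, c, d), 2,
                                                  byrow = TRUE),
                                           correct = FALSE))
  expect_equal(tw2$statistic[1], unname(ct$statistic), tolerance = 1e-10)

  ## BH on the textbook example
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  ## BH oracle equivalence on random vectors
  set.seed(31)
  for (i in 1:20) {
    p <- runif(200)^2
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
})

test_that("chi-squared p and q match brute force on random windows", {
  set.seed(32)
  n <- 1000
  wt <- make_cov(rpois(n, 100)); wt$count_norm <- wt$count
  mu <- make_cov(rpois(n, 100)); mu$count_norm <- mu$count
  tw <- test_windows(wt, mu)
  Tw <- sum(wt$count); Tm <- sum(mu$count)
  p_brute <- vapply(seq_len(n), function(i) {
    m <- matrix(c(wt$count[i], Tw - wt$count[i],
                  mu$count[i], Tm - mu$count[i]), 2, byrow = TRUE)
    suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
  }, numeric(1))
  expect_lt(max(abs(tw$p - p_brute)), 1e-10)
  expect_lt(max(abs(tw$q - bh_stepup(p_brute))), 1e-10)
})

test_that("call merging enforces direction, span and support rules", {
  tmpl <- tibble::tibble(
    chrom = "chr", start = c(0, 100, 200), end = c(200, 300, 400),
    wt_count = 100, mut_count = 200, ratio = 2, statistic = 50,
    p = 1e-10, q = 1e-9, significant = TRUE, direction = "gain")
  ## 3 windows spanning 400 bp: rejected by the strict > 500 rule
  expect_equal(nrow(merge_calls(tmpl)), 0)
  ## 5 windows spanning 600 bp: one call
  five <- tibble::tibble(
    chrom = "chr", start = seq(0, 400, 100), end = seq(200, 600, 100),
    wt_count = 100, mut_count = 200, ratio = 2, statistic = 50,
    p = 1e-10, q = 1e-9, significant = TRUE, direction = "gain")
  calls <- merge_calls(five)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 0)
  expect_equal(calls$end, 600)
  expect_equal(calls$n_windows, 5L)
  expect_equal(calls$direction, "gain")
  ## a loss run adjacent to a gain run is never merged across direction
  mixed <- rbind(five,
                 within(five, {start <- start + 600; end <- end + 600
                               direction <- "loss"; ratio <- 0.5}))
  calls2 <- merge_calls(mixed)
  expect_equal(nrow(calls2), 2)
  expect_setequal(calls2$direction, c("gain", "loss"))
})

test_that("null sample pairs yield no CNV calls under Poisson noise", {
  g <- simulate_genome(c(chrI = 600000, chrII = 500000), g4_density = 0,
                       mt_chrom = NULL, seed = 41)
  for (s in 1:3) {
    wt <- simulate_coverage(g, depth = 100, noise = "poisson",
                            seed = 500 + s)
    mu <- simulate_coverage(g, depth = 100, noise = "poisson",
                            seed = 600 + s)
    expect_equal(nrow(call_cnvs(wt, mu)), 0)
  }
})

test_that("GC bias inflates calls only when left uncorrected", {
  g <- simulate_genome(c(chrI = 600000, chrII = 600000), g4_density = 0,
                       mt_chrom = NULL, seed = 42)
  ## library-specific bias: control unbiased, mutant biased
  wt <- simulate_coverage(g, depth = 500, gc_bias = "identity",
                          noise = "poisson", seed = 43)
  mu <- simulate_coverage(g, depth = 500, gc_bias = "quadratic",
                          noise = "poisson", seed = 44)
  uncorrected <- call_cnvs(wt, mu, gc_normalize = FALSE)
  corrected <- call_cnvs(wt, mu, gc_normalize = TRUE)
  expect_gt(nrow(uncorrected), 10)
  expect_lte(nrow(corrected), 1)
})

test_that("whole-chromosome duplications are flagged from depth ratios", {
  g <- simulate_genome(c(chrI = 150000, chrII = 150000, chrIII = 150000),
                       g4_density = 0, mt_chrom = NULL, seed = 51)
  wt <- simulate_coverage(g, depth = 100, gc_bias = "identity",
                          noise = "poisson", seed = 52)
  ## identical sample: all ratios 1, no flags
  pl0 <- chromosome_ploidy(wt, wt)
  expect_equal(pl0$ratio, rep(1, 3))
  expect_false(any(pl0$duplicated))
  ## planted duplication of chrII
  tr <- cnv_truth(whole_chrom_dups = "chrII")
  mu <- simulate_coverage(g, tr, depth = 100, gc_bias = "identity",
                          noise = "poisson", seed = 53)
  pl <- chromosome_ploidy(wt, mu)
  expect_true(pl$duplicated[pl$chrom == "chrII"])
  expect_false(any(pl$duplicated[pl$chrom != "chrII"]))
  expect_gt(pl$ratio[pl$chrom == "chrII"], 1.8)
  expect_lt(pl$ratio[pl$chrom == "chrII"], 2.2)
  ## a global 2x depth difference cancels out
  mu2 <- simulate_coverage(g, depth = 200, gc_bias = "identity",
                           noise = "poisson", seed = 54)
  pl2 <- chromosome_ploidy(wt, mu2)
  expect_false(any(pl2$duplicated))
  expect_true(all(abs(pl2$ratio - 1) < 0.1))
})

test_that("mtDNA copy number is an RPKM ratio with the stated direction", {
  ## uniform depth everywhere: copy number exactly 1
  feats <- tibble::tibble(name = c("g1", "g2", "mt"),
                          chrom = c("c1", "c1", "chrM"),
                          start = 0, end = c(1000, 2000, 5000),
                          length = c(1000, 2000, 5000),
                          count = c(100, 200, 500))
  out <- mtdna_copy_number(feats, total_mapped = 800, mt_names = "mt")
  expect_equal(out$copy_number, 1)
  ## mt at 20x per-base depth
  feats20 <- feats
  feats20$count[3] <- 500 * 20
  out20 <- mtdna_copy_number(feats20, total_mapped = 10300, mt_names = "mt")
  expect_equal(out20$copy_number, 20)
  ## relative copy number across samples: 5x vs control 20x -> 0.25
  rel <- mtdna_copy_number(
    list(control = feats20,
         mutant = within(feats, count[3] <- 500 * 5)),
    total_mapped = c(10300, 3300), mt_names = "mt", control = "control")
  expect_equal(rel$relative_copy_number[rel$sample_id == "mutant"], 0.25)
  expect_error(mtdna_copy_number(feats, total_mapped = 0, mt_names = "mt"),
               "positive")
})

test_that("feature counts recover planted per-gene depth from windows", {
  g <- simulate_genome(c(chrI = 200000, chrM = 40000), g4_density = 0,
                       seed = 61)
  cov <- simulate_coverage(g, depth = 100, gc_bias = "identity",
                           noise = "poisson", seed = 62)
  mtf <- tibble::tibble(name = "chrM", chrom = "chrM", start = 0, end = 40000)
  fc <- dplyr::bind_rows(feature_counts(cov, g$single_copy_genes),
                         feature_counts(cov, mtf))
  cn <- mtdna_copy_number(fc, total_mapped = attr(cov, "total_mapped"),
                          mt_names = "chrM")
  expect_equal(cn$copy_number, 20, tolerance = 0.03)
})
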