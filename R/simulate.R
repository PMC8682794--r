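## Seeded generators for every input the pipeline consumes. All generators
## are pure functions of (config, seed): the caller's RNG state is restored
## on exit.

eval_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Default GC-bias curve
#'
#' Unimodal quadratic multiplier peaking at GC 0.40, falling to its floor of
#' 0.5 at GC 0.2 and 0.6 -- i.e. the \[0.5, 1\] range is realized across the
#' GC span that 200 bp windows of a yeast-like genome actually occupy. An
#' Illumina-like bias strong enough that coverage depends visibly on GC.
#'
#' @param gc GC fraction in \[0, 1\].
#' @return Multiplier in \[0.5, 1\].
#' @export
gc_bias_quadratic <- function(gc) {
  pmax(0.5, 1 - 12.5 * (gc - 0.4)^2)
}

#' Simulate a yeast-like genome with planted G4 motifs
#'
#' Generates per-chromosome nucleotide sequences whose local GC fraction
#' follows `gc_profile`, plants G4 motifs (>= 4 G-runs of >= 3 nt with short
#' loops) at recorded coordinates, and lays out non-overlapping single-copy
#' nuclear genes used for RPKM-based mitochondrial copy-number estimation.
#' One chromosome (default `chrM`) is mitochondrial. With `mask_g4 = TRUE`
#' (default) accidental G/C runs of 3+ in the background are broken so the
#' planted motifs are the only scanner hits and enrichment ground truth is
#' exact.
#'
#' @param chrom_sizes Named lengths in bp. Default: four nuclear chromosomes
#'   (150-300 kb) plus an 86 kb mitochondrial chromosome, a scaled-down
#'   S. cerevisiae-like layout.
#' @param gc_profile Either a single GC fraction or a function of base
#'   position (bp) returning the local GC fraction.
#' @param g4_density Planted motifs per 10 kb (default 0.5).
#' @param n_genes Number of single-copy nuclear genes to lay out.
#' @param mt_chrom Name of the mitochondrial chromosome (`NULL` for none).
#' @param mask_g4 Break accidental G/C runs outside planted motifs.
#' @param seed Integer seed (required for reproducibility).
#' @return An object of class `sim_genome`: list with `sequences` (named
#'   character), `chrom_sizes`, `g4` (interval tibble with strand and
#'   sequence), `single_copy_genes`, `mt_chrom`, and the config echo.
#' @export
simulate_genome <- function(chrom_sizes = c(chrI = 250000, chrII = 200000,
                                            chrIII = 180000, chrIV = 150000,
                                            chrM = 86000),
                            gc_profile = function(pos) 0.38 + 0.10 * sin(2 * pi * pos / 40000),
                            g4_density = 0.5, n_genes = 60,
                            mt_chrom = "chrM", mask_g4 = TRUE, seed) {
  if (missing(seed)) abort("simulate_genome needs an explicit seed")
  if (any(chrom_sizes <= 0)) abort("chromosome sizes must be positive")
  if (any(chrom_sizes < 200)) {
    abort("chromosome shorter than one 200 bp window; enlarge chrom_sizes")
  }
  if (!is.null(mt_chrom) && !mt_chrom %in% names(chrom_sizes)) mt_chrom <- NULL
  gc_fun <- if (is.function(gc_profile)) gc_profile else function(pos) {
    rep(gc_profile, length(pos))
  }
  eval_with_seed(seed, {
    bases <- c("A", "T", "C", "G")
    seqs <- list(); g4_list <- list()
    for (chr in names(chrom_sizes)) {
      L <- chrom_sizes[[chr]]
      p <- pmin(0.95, pmax(0.05, gc_fun(seq_len(L))))
      is_gc <- stats::runif(L) < p
      pick2 <- stats::runif(L) < 0.5
      chars <- bases[1L + is_gc * 2L + pick2]
      if (mask_g4) {
        chars <- break_runs(chars, "G", "T")
        chars <- break_runs(chars, "C", "A")
      }
      ## plant motifs, non-overlapping, fully inside the chromosome
      n_g4 <- stats::rpois(1, g4_density * L / 10000)
      taken <- IRanges::IRanges()
      for (i in seq_len(n_g4)) {
        motif <- random_g4_motif()
        w <- nchar(motif)
        for (try in 1:50) {
          s <- sample.int(L - w, 1)   # 0-based start
          cand <- IRanges::IRanges(s + 1L, s + w)
          if (length(taken) == 0L ||
              !any(IRanges::overlapsAny(cand, taken, maxgap = 30L))) {
            strand <- sample(c("+", "-"), 1)
            ins <- if (strand == "+") motif else revcomp(motif)
            chars[(s + 1):(s + w)] <- strsplit(ins, "")[[1]]
            taken <- c(taken, cand)
            g4_list[[length(g4_list) + 1L]] <-
              tibble(chrom = chr, start = s, end = s + w,
                     strand = strand, sequence = motif)
            break
          }
        }
      }
      seqs[[chr]] <- paste(chars, collapse = "")
    }
    g4 <- if (length(g4_list)) arrange(bind_rows(g4_list), .data$chrom,
                                       .data$start) else
      tibble(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), sequence = character())
    ## single-copy nuclear genes (1-2 kb, non-overlapping)
    nuclear <- setdiff(names(chrom_sizes), mt_chrom)
    genes <- list()
    sizes_n <- chrom_sizes[nuclear]
    for (i in seq_len(n_genes)) {
      chr <- sample(nuclear, 1, prob = sizes_n)
      w <- sample(1000:2000, 1)
      s <- sample.int(chrom_sizes[[chr]] - w, 1)
      genes[[i]] <- tibble(gene = sprintf("gene%03d", i), chrom = chr,
                           start = s, end = s + w)
    }
    genes <- bind_rows(genes)
    ## drop overlapping gene placements (keep first comer)
    if (nrow(genes)) {
      gr <- intervals_to_gr(genes)
      ov <- GenomicRanges::findOverlaps(gr, gr)
      dup <- unique(S4Vectors::queryHits(ov)[S4Vectors::queryHits(ov) >
                                               S4Vectors::subjectHits(ov)])
      if (length(dup)) genes <- genes[-dup, , drop = FALSE]
    }
    structure(list(sequences = unlist(seqs), chrom_sizes = chrom_sizes,
                   g4 = g4, single_copy_genes = genes, mt_chrom = mt_chrom,
                   gc_profile = gc_fun, g4_density = g4_density,
                   mask_g4 = mask_g4, seed = seed),
              class = "sim_genome")
  })
}

## Break every >=3 homopolymer run of `base` by substituting offsets 2,5,8,...
break_runs <- function(chars, base, sub) {
  r <- rle(chars == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long <- which(r$values & r$lengths >= 3L)
  for (i in long) {
    off <- seq(starts[i] + 2L, ends[i], by = 3L)
    chars[off] <- sub
  }
  chars
}

random_g4_motif <- function() {
  runs <- sample(4:5, 1)
  run_len <- sample(3:4, runs, replace = TRUE)
  loops <- vapply(seq_len(runs - 1), function(i) {
    paste(sample(c("A", "T"), sample(1:7, 1), replace = TRUE), collapse = "")
  }, character(1))
  paste0(paste0(strrep("G", run_len[-runs]), loops, collapse = ""),
         strrep("G", run_len[runs]))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("Simulated genome:", length(x$chrom_sizes), "chromosomes,",
      sum(x$chrom_sizes), "bp;", nrow(x$g4), "planted G4 motifs;",
      nrow(x$single_copy_genes), "single-copy genes",
      if (!is.null(x$mt_chrom)) paste0("; mt = ", x$mt_chrom) else "", "\n")
  invisible(x)
}

#' Ground-truth copy-number alterations for a simulated sample
#'
#' @param intervals Interval tibble with a `copy` column (multipliers >= 0,
#'   e.g. 0, 0.5, 2, 3); intervals must not overlap within the sample.
#' @param whole_chrom_dups Chromosome names duplicated in full (copy 2).
#' @param mt_multiplier Depth multiplier for the mitochondrial chromosome
#'   (default 20, i.e. ~20 mtDNA copies per haploid nuclear genome).
#' @return `cnv_truth` object.
#' @export
cnv_truth <- function(intervals = NULL, whole_chrom_dups = character(),
                      mt_multiplier = 20) {
  if (is.null(intervals)) {
    intervals <- tibble(chrom = character(), start = numeric(),
                        end = numeric(), copy = numeric())
  }
  intervals <- as_tibble(intervals)
  if (nrow(intervals)) {
    if (!"copy" %in% names(intervals)) abort("truth intervals need a copy column")
    if (any(intervals$copy < 0)) abort("copy multipliers must be >= 0")
    intervals <- as_intervals(intervals, "truth intervals")
    gr <- intervals_to_gr(intervals)
    if (any(GenomicRanges::countOverlaps(gr, gr) > 1)) {
      abort("truth intervals must not overlap")
    }
  }
  structure(list(intervals = intervals, whole_chrom_dups = whole_chrom_dups,
                 mt_multiplier = mt_multiplier),
            class = "cnv_truth")
}

#' Draw a random set of CNVs on a simulated genome
#'
#' Plants `n` non-overlapping segmental CNVs on nuclear chromosomes with
#' spans and copy multipliers drawn uniformly from the supplied choices.
#'
#' @param genome A `sim_genome`.
#' @param n Number of CNVs.
#' @param span_range Min/max span in bp.
#' @param copies Copy multipliers to draw from.
#' @param seed Integer seed.
#' @inheritParams cnv_truth
#' @return `cnv_truth` object.
#' @export
simulate_cnv_truth <- function(genome, n = 20, span_range = c(800, 3000),
                               copies = c(0, 0.5, 2),
                               whole_chrom_dups = character(),
                               mt_multiplier = 20, seed) {
  if (missing(seed)) abort("simulate_cnv_truth needs an explicit seed")
  nuclear <- setdiff(names(genome$chrom_sizes), genome$mt_chrom)
  sizes <- genome$chrom_sizes[nuclear]
  eval_with_seed(seed, {
    out <- list(); taken <- list()
    guard <- 0
    while (length(out) < n && guard < 10000) {
      guard <- guard + 1
      chr <- sample(nuclear, 1, prob = sizes)
      w <- round(stats::runif(1, span_range[1], span_range[2]))
      s <- sample.int(sizes[[chr]] - w, 1)
      cand <- tibble(chrom = chr, start = s, end = s + w,
                     copy = sample(copies, 1))
      ok <- TRUE
      if (length(out)) {
        prev <- bind_rows(out)
        prev <- prev[prev$chrom == chr, , drop = FALSE]
        ## 2 kb clearance so calls stay unambiguous at window resolution
        if (nrow(prev) && any(prev$start < cand$end + 2000 &
                              cand$start < prev$end + 2000)) ok <- FALSE
      }
      if (ok) out[[length(out) + 1L]] <- cand
    }
    cnv_truth(bind_rows(out), whole_chrom_dups = whole_chrom_dups,
              mt_multiplier = mt_multiplier)
  })
}

#' Simulate windowed read-depth coverage for one sample
#'
#' The expected count of window w is
#' `depth * copy(w) * gc_bias(gc(w))` (times the mitochondrial multiplier on
#' the mt chromosome), with `copy(w)` the overlap-fraction-weighted copy
#' multiplier from `truth`. Counts are drawn as Poisson or negative-binomial
#' (variance `mu + dispersion * mu^2`).
#'
#' @param genome A `sim_genome`.
#' @param truth A [cnv_truth()] (or `NULL` for a plain euploid sample).
#' @param depth Mean reads per window at copy 1 and no bias.
#' @param gc_bias `"quadratic"` (default, [gc_bias_quadratic()]),
#'   `"identity"`, or a function gc -> multiplier (> 0 on \[0, 1\]).
#' @param noise `"negbin"` (default) or `"poisson"`.
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param window_bp,step_bp Window grid parameters.
#' @param sample_id Sample label.
#' @param seed Integer seed.
#' @return Coverage tibble (`chrom`, `start`, `end`, `gc`, `count`) with
#'   attributes `total_mapped`, `sample_id` and `truth`.
#' @export
simulate_coverage <- function(genome, truth = NULL, depth = 100,
                              gc_bias = c("quadratic", "identity"),
                              noise = c("negbin", "poisson"),
                              dispersion = 0.1, window_bp = 200,
                              step_bp = 100, sample_id = "sample", seed) {
  if (missing(seed)) abort("simulate_coverage needs an explicit seed")
  if (depth < 0) abort("depth must be >= 0")
  noise <- match.arg(noise)
  if (noise == "negbin" && dispersion <= 0) {
    abort("negative-binomial dispersion must be > 0")
  }
  bias_fun <- if (is.function(gc_bias)) gc_bias else
    switch(match.arg(gc_bias),
           quadratic = gc_bias_quadratic,
           identity = function(gc) rep(1, length(gc)))
  probe <- bias_fun(seq(0, 1, by = 0.05))
  if (any(!is.finite(probe)) || any(probe <= 0)) {
    abort("gc_bias must return positive multipliers over [0, 1]")
  }
  if (is.null(truth)) truth <- cnv_truth()
  win <- make_windows(genome$chrom_sizes, window_bp, step_bp)
  win <- window_gc(genome$sequences, win)
  copy <- rep(1, nrow(win))
  if (length(truth$whole_chrom_dups)) {
    copy[win$chrom %in% truth$whole_chrom_dups] <- 2
  }
  if (!is.null(genome$mt_chrom)) {
    copy[win$chrom == genome$mt_chrom] <-
      copy[win$chrom == genome$mt_chrom] * truth$mt_multiplier
  }
  if (nrow(truth$intervals)) {
    wgr <- intervals_to_gr(win)
    tgr <- intervals_to_gr(truth$intervals)
    hits <- GenomicRanges::findOverlaps(wgr, tgr)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      ov <- GenomicRanges::width(GenomicRanges::pintersect(wgr[qh], tgr[sh]))
      frac <- ov / window_bp
      copy[qh] <- copy[qh] + frac * (truth$intervals$copy[sh] - 1)
    }
  }
  mu <- depth * copy * bias_fun(win$gc)
  mu[is.na(mu)] <- 0
  eval_with_seed(seed, {
    counts <- if (noise == "poisson") stats::rpois(length(mu), mu) else
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    out <- mutate(win, count = as.numeric(counts))
    attr(out, "total_mapped") <- sum(counts)
    attr(out, "sample_id") <- sample_id
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate a Luria-Delbruck fluctuation experiment
#'
#' Per-culture mutant counts are drawn by inverse-CDF sampling from the
#' Ma-Sandri-Sarkar pmf (see [mss_pmf()]); a plating fraction < 1 is applied
#' by exact binomial thinning of each drawn count. Because the distribution
#' has a quadratic tail, the pmf support is extended adaptively and draws
#' falling beyond the support cap are clamped to it (probability ~ m/cap).
#'
#' @param m Expected mutations per culture (>= 0).
#' @param n_cultures Number of parallel cultures (>= 1).
#' @param Nt Viable cells per culture.
#' @param plating_fraction Fraction of each culture plated, in (0, 1\].
#' @param strain Strain label.
#' @param seed Integer seed.
#' @return A `fluctuation_experiment`: tibble (`culture`, `mutants`) with
#'   attributes `Nt`, `plating_fraction`, `strain`, `m_true`.
#' @export
simulate_fluctuation <- function(m, n_cultures, Nt = 2e8,
                                 plating_fraction = 1, strain = "strain",
                                 seed) {
  if (missing(seed)) abort("simulate_fluctuation needs an explicit seed")
  if (m < 0) abort("m must be >= 0")
  if (n_cultures < 1) abort("need at least one culture")
  counts <- if (m == 0) rep(0L, n_cultures) else eval_with_seed(seed, {
    u <- stats::runif(n_cultures)
    r_max <- 2048L
    repeat {
      p <- mss_pmf(m, r_max = r_max)
      cdf <- cumsum(p)
      if (max(u) <= cdf[length(cdf)] || r_max >= 65536L) break
      r_max <- r_max * 2L
    }
    r <- findInterval(u, cdf, left.open = TRUE)   # counts 0..r_max
    r <- pmin(r, r_max)
    if (plating_fraction < 1) r <- stats::rbinom(length(r), r, plating_fraction)
    r
  })
  out <- tibble(culture = seq_len(n_cultures), mutants = as.integer(counts))
  structure(out, Nt = Nt, plating_fraction = plating_fraction,
            strain = strain, m_true = m,
            class = c("fluctuation_experiment", class(out)))
}

#' Simulate paired UV absorbance spectra (20 and 90 degrees C)
#'
#' Emits spectra whose thermal difference spectrum (TDS) has the shape
#' expected for the requested species: a G4 TDS is positive below 290 nm and
#' negative above with the zero crossing exactly at 290 nm; duplex and
#' single-stranded TDS are non-negative everywhere (pure hyperchromicity)
#' before noise.
#'
#' @param kind `"g4"`, `"duplex"` or `"ss"`.
#' @param noise_sd Gaussian noise sd as a fraction of the low-temperature
#'   maximum absorbance (applied independently to both spectra).
#' @param wavelengths Wavelength grid in nm (must cover 220-320).
#' @param seed Integer seed (needed when `noise_sd > 0`).
#' @return Tibble (`wavelength`, `a_low`, `a_high`) with attributes
#'   `tds_true` (analytic normalized TDS), `a_max_true` and `kind`.
#' @export
simulate_spectra <- function(kind = c("g4", "duplex", "ss"), noise_sd = 0,
                             wavelengths = 220:320, seed = NULL) {
  kind <- match.arg(kind)
  if (min(wavelengths) > 220 || max(wavelengths) < 320) {
    abort("wavelength grid must cover 220-320 nm")
  }
  wl <- as.numeric(wavelengths)
  low <- 0.9 * exp(-((wl - 258) / 27)^2) + 0.08 * exp(-((wl - 230) / 12)^2)
  a_max <- max(low)
  tds_rel <- switch(kind,
    g4 = 0.013 * (290 - wl) *
      (exp(-((wl - 273) / 14)^2) + 2.6 * exp(-((wl - 296) / 7)^2)),
    duplex = 0.28 * exp(-((wl - 260) / 25)^2),
    ss = 0.18 * exp(-((wl - 266) / 32)^2))
  high <- low + tds_rel * a_max
  if (noise_sd > 0) {
    if (is.null(seed)) abort("noisy spectra need a seed")
    noise <- eval_with_seed(seed, {
      list(lo = stats::rnorm(length(wl), 0, noise_sd * a_max),
           hi = stats::rnorm(length(wl), 0, noise_sd * a_max))
    })
    low <- low + noise$lo
    high <- high + noise$hi
  }
  out <- tibble(wavelength = wl, a_low = low, a_high = high)
  structure(out, tds_true = tibble(wavelength = wl, tds = tds_rel),
            a_max_true = a_max, kind = kind,
            class = c("sim_spectra", class(out)))
}

#' Simulate a Langmuir biosensor binding curve
#'
#' Within each concentration step at concentration c the surface density
#' relaxes exponentially toward the isotherm plateau
#' `sigma_max * c / (c + Kd)` at rate `kon * c + koff`, continuously across
#' steps. The default schedule is the five-spike series 0.08, 0.4, 2, 10 and
#' 50 nM.
#'
#' @param kon Association rate, 1/(nM s) (> 0).
#' @param koff Dissociation rate, 1/s (> 0).
#' @param sigma_max Surface density at saturation.
#' @param conc_steps Tibble with `time` (step start, s) and `conc` (nM).
#' @param t_end,dt End time and sampling interval (s).
#' @param noise_sd Multiplicative Gaussian noise sd (fraction of signal).
#' @param seed Integer seed (needed when `noise_sd > 0`).
#' @return Tibble (`time`, `sigma`, `conc`) with attribute `params`.
#' @export
simulate_binding <- function(kon = 1e-3, koff = 5e-3, sigma_max = 1,
                             conc_steps = tibble(
                               time = c(0, 600, 1200, 1800, 2400),
                               conc = c(0.08, 0.4, 2, 10, 50)),
                             t_end = 3000, dt = 2, noise_sd = 0, seed = NULL) {
  if (kon <= 0 || koff <= 0) abort("kon and koff must be > 0")
  if (is.unsorted(conc_steps$time, strictly = TRUE)) {
    abort("step times must be strictly increasing")
  }
  kd <- koff / kon
  times <- seq(conc_steps$time[1], t_end, by = dt)
  sigma <- numeric(length(times))
  conc <- numeric(length(times))
  sigma0 <- 0
  bounds <- c(conc_steps$time[-1], Inf)
  for (i in seq_len(nrow(conc_steps))) {
    c_i <- conc_steps$conc[i]
    idx <- which(times >= conc_steps$time[i] & times < bounds[i])
    if (!length(idx)) next
    s_eq <- if (c_i == 0) 0 else sigma_max * c_i / (c_i + kd)
    k <- kon * c_i + koff
    tt <- times[idx] - conc_steps$time[i]
    sigma[idx] <- s_eq + (sigma0 - s_eq) * exp(-k * tt)
    conc[idx] <- c_i
    ## state at the end of the step, for continuity
    t_next <- min(bounds[i], t_end) - conc_steps$time[i]
    sigma0 <- s_eq + (sigma0 - s_eq) * exp(-k * t_next)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) abort("noisy binding curves need a seed")
    sigma <- eval_with_seed(seed, {
      sigma * (1 + stats::rnorm(length(sigma), 0, noise_sd))
    })
  }
  out <- tibble(time = times, sigma = sigma, conc = conc)
  structure(out, params = list(kon = kon, koff = koff, kd = kd,
                               sigma_max = sigma_max),
            class = c("sim_binding", class(out)))
}

#' Write a simulated genome to disk
#'
#' FASTA for the sequences, BED for planted G4 motifs and single-copy genes,
#' JSON for the config echo -- everything downstream steps or external tools
#' need.
#'
#' @param genome A `sim_genome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$sequences),
                              file.path(dir, "genome.fa"))
  write_bed(mutate(genome$g4, name = paste0("g4_", row_number()), score = 0),
            file.path(dir, "planted_g4.bed"))
  write_bed(mutate(genome$single_copy_genes, name = .data$gene, score = 0),
            file.path(dir, "single_copy_genes.bed"))
  jsonlite::write_json(
    list(chrom_sizes = as.list(genome$chrom_sizes),
         mt_chrom = genome$mt_chrom, g4_density = genome$g4_density,
         mask_g4 = genome$mask_g4, seed = genome$seed),
    file.path(dir, "genome_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
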