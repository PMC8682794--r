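#' Ma-Sandri-Sarkar probability mass function
#'
#' Luria-Delbruck mutant-count distribution for expected mutations per
#' culture m, by the MSS recursion: p_0 = exp(-m) and, for r >= 1,
#' p_r = (m / r) * sum_{i=0}^{r-1} p_i / (r - i + 1).
#'
#' The distribution has a quadratic tail, p_r -> m / (r (r + 1)), so the
#' mass beyond any finite truncation is ~ m / r_max and cannot be driven to
#' machine precision; the analytic tail estimate m / (r_max + 1) is attached
#' as attribute `tail_mass`. p_0 is exact at any truncation.
#'
#' @param m Expected mutations per culture (>= 0).
#' @param r_max Largest count computed (support is 0..r_max).
#' @return Numeric vector p_0..p_r_max with attribute `tail_mass`.
#' @export
mss_pmf <- function(m, r_max = 1000) {
  if (m < 0) abort("m must be >= 0")
  r_max <- as.integer(r_max)
  p <- mss_pmf_cpp(m, r_max)
  attr(p, "tail_mass") <- if (m > 0) m / (r_max + 1) else 0
  p
}

## Log-likelihood with censoring of jackpot counts at `cap`: the pmf has a
## quadratic tail, so counts beyond the cap contribute through the tail
## probability P(X >= cap) instead of requiring an O(cap^2) recursion out to
## the largest jackpot.
mss_loglik <- function(m, counts, cap = 5000) {
  if (m <= 0) return(if (all(counts == 0)) 0 else -Inf)
  cens <- counts >= cap
  r_top <- if (all(cens)) cap else max(counts[!cens])
  p <- mss_pmf(m, r_max = max(r_top, if (any(cens)) cap - 1 else 0))
  ll <- sum(log(pmax(p[counts[!cens] + 1], .Machine$double.xmin)))
  if (any(cens)) {
    tail_p <- max(1 - sum(p[seq_len(cap)]), .Machine$double.xmin)
    ll <- ll + sum(cens) * log(tail_p)
  }
  ll
}

## pmf of observed (plated) counts under binomial thinning with fraction f:
## q_k = sum_r p_r * dbinom(k, r, f), truncated at r_max.
mss_pmf_thinned <- function(m, r_max, fraction, k_max = r_max) {
  p <- mss_pmf(m, r_max = r_max)
  mss_thin_cpp(as.numeric(p), fraction, as.integer(k_max))
}

#' MSS maximum-likelihood estimate of the mutation number and rate
#'
#' Maximizes the Luria-Delbruck log-likelihood of the per-culture mutant
#' counts over m by bounded scalar optimization; the 95% confidence
#' interval comes from the profile-likelihood drop of 1.92 log-units
#' (chi-squared 1 df). The mutation rate is m / Nt per cell per
#' generation-equivalent. A plating fraction < 1 is handled by exact
#' binomial thinning of the pmf (`plating_method = "thin"`) or, for
#' compatibility with rescaling tools, by dividing the estimated m by the
#' fraction (`"rescale"`).
#'
#' @param x A `fluctuation_experiment` (from [simulate_fluctuation()] or
#'   [as_fluctuation()]), or a vector of per-culture mutant counts.
#' @param Nt Viable cells per culture (taken from `x` when present).
#' @param plating_fraction Fraction of each culture plated.
#' @param plating_method `"thin"` (exact) or `"rescale"`.
#' @param conf_level Confidence level for the profile interval.
#' @return A `rate_estimate`: list with `m`, `ci` (on m), `rate`,
#'   `rate_ci`, `loglik`, `n_cultures`, `Nt`.
#' @export
mss_mle <- function(x, Nt = NULL, plating_fraction = NULL,
                    plating_method = c("thin", "rescale"),
                    conf_level = 0.95) {
  plating_method <- match.arg(plating_method)
  if (inherits(x, "fluctuation_experiment")) {
    counts <- x$mutants
    Nt <- Nt %||% attr(x, "Nt", exact = TRUE)
    plating_fraction <- plating_fraction %||%
      attr(x, "plating_fraction", exact = TRUE) %||% 1
  } else {
    counts <- as.integer(x)
    plating_fraction <- plating_fraction %||% 1
  }
  if (is.null(Nt) || Nt <= 0) abort("Nt (cells per culture) must be positive")
  if (any(counts < 0)) abort("mutant counts must be non-negative")
  n <- length(counts)
  drop <- stats::qchisq(conf_level, df = 1) / 2
  if (all(counts == 0)) {
    est <- structure(list(m = 0, ci = c(0, drop_upper_zero(n, drop)),
                          rate = 0, loglik = 0, n_cultures = n, Nt = Nt,
                          plating_fraction = plating_fraction),
                     class = "rate_estimate")
    est$rate_ci <- est$ci / Nt
    return(est)
  }
  thin <- plating_fraction < 1 && plating_method == "thin"
  r_cap <- max(counts)
  ll <- if (thin) {
    function(m) {
      if (m <= 0) return(-Inf)
      ## thin from a generously larger latent support
      r_lat <- min(max(50L, ceiling(r_cap / plating_fraction * 3)), 15000L)
      q <- mss_pmf_thinned(m, r_lat, plating_fraction)
      sum(log(pmax(q[counts + 1], .Machine$double.xmin)))
    }
  } else {
    function(m) mss_loglik(m, counts)
  }
  ## bracket from the p0 method (fraction of zero cultures)
  p0_hat <- max(mean(counts == 0), 0.5 / n)
  m0 <- -log(p0_hat)
  m_hi <- max(2 * (m0 + 5), 1)
  for (tries in 1:10) {
    opt <- stats::optimize(ll, interval = c(1e-9, m_hi), maximum = TRUE,
                           tol = 1e-8)
    if (opt$maximum < 0.95 * m_hi) break
    m_hi <- m_hi * 2
  }
  m_hat <- opt$maximum
  ll_max <- opt$objective
  if (!is.finite(ll_max)) {
    abort("likelihood not finite at the optimum; check counts (all at the truncation cap?)")
  }
  target <- function(m) ll(m) - (ll_max - drop)
  lo <- if (target(1e-9) > 0) 0 else
    stats::uniroot(target, c(1e-9, m_hat), tol = 1e-8)$root
  hi_bound <- m_hi
  while (target(hi_bound) > 0 && hi_bound < 1e6) hi_bound <- hi_bound * 2
  hi <- if (target(hi_bound) > 0) hi_bound else
    stats::uniroot(target, c(m_hat, hi_bound), tol = 1e-8)$root
  if (plating_fraction < 1 && plating_method == "rescale") {
    m_hat <- m_hat / plating_fraction
    lo <- lo / plating_fraction
    hi <- hi / plating_fraction
  }
  structure(list(m = m_hat, ci = c(lo, hi), rate = m_hat / Nt,
                 rate_ci = c(lo, hi) / Nt, loglik = ll_max,
                 n_cultures = n, Nt = Nt,
                 plating_fraction = plating_fraction),
            class = "rate_estimate")
}

## upper profile bound on m when every culture has zero mutants:
## loglik(m) = -n m (p0^n), drop 1.92 => m_hi = drop / n
drop_upper_zero <- function(n, drop) drop / n

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("MSS-MLE: m = %.4g (95%% CI %.4g-%.4g), rate = %.3g per cell (Nt = %.3g, %d cultures)\n",
              x$m, x$ci[1], x$ci[2], x$rate, x$Nt, x$n_cultures))
  invisible(x)
}

#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble(term = c("m", "rate"), estimate = c(x$m, x$rate),
         conf.low = c(x$ci[1], x$rate_ci[1]),
         conf.high = c(x$ci[2], x$rate_ci[2]))
}

#' @export
glance.rate_estimate <- function(x, ...) {
  tibble(m = x$m, rate = x$rate, logLik = x$loglik,
         n_cultures = x$n_cultures, Nt = x$Nt)
}

#' Build a fluctuation experiment from counts
#'
#' @param mutants Per-culture mutant counts.
#' @param Nt Viable cells per culture.
#' @param plating_fraction Fraction plated, in (0, 1].
#' @param strain Strain label.
#' @return A `fluctuation_experiment` tibble.
#' @export
as_fluctuation <- function(mutants, Nt, plating_fraction = 1,
                           strain = "strain") {
  if (length(mutants) < 1) abort("need at least one culture")
  if (Nt <= 0) abort("Nt must be positive")
  out <- tibble(culture = seq_along(mutants), mutants = as.integer(mutants))
  structure(out, Nt = Nt, plating_fraction = plating_fraction,
            strain = strain,
            class = c("fluctuation_experiment", class(out)))
}

#' Fold enrichment between two GCR rate estimates
#'
#' The fold enrichment is the ratio of mutation rates (numerator strain
#' over denominator strain, e.g. mutant over wild type carrying the same
#' cassette). With replicate experiments, per-replicate folds are paired in
#' order and their mean reported.
#'
#' @param num,den A `rate_estimate` or list of replicate `rate_estimate`s.
#' @return A `fold_enrichment` tibble: one row per replicate pair with
#'   `fold`, plus attribute `mean_fold`.
#' @export
fold_enrichment <- function(num, den) {
  as_list <- function(x) if (inherits(x, "rate_estimate")) list(x) else x
  num <- as_list(num); den <- as_list(den)
  if (length(num) != length(den)) {
    abort("need the same number of replicate estimates on both sides")
  }
  folds <- purrr::map2_dbl(num, den, function(a, b) {
    if (b$rate == 0) {
      warn("denominator rate is 0; fold undefined (NA)")
      return(NA_real_)
    }
    a$rate / b$rate
  })
  out <- tibble(replicate = seq_along(folds),
                rate_num = purrr::map_dbl(num, "rate"),
                rate_den = purrr::map_dbl(den, "rate"),
                fold = folds)
  structure(out, mean_fold = mean(folds, na.rm = TRUE),
            class = c("fold_enrichment", class(out)))
}

#' Pfaffl efficiency-corrected qPCR enrichment
#'
#' For the target locus and the reference locus (e.g. HHT2 as internal
#' standard), delta-Ct = Ct_input - Ct_IP after correcting the input Ct for
#' its dilution (an input diluted 1:`dilution` is corrected by
#' -log_E(dilution)); the fold enrichment is
#' E_target^dCt_target / E_ref^dCt_ref. Efficiencies outside the accepted
#' band (1.9-2.1, i.e. 95-105% PCR efficiency) are rejected unless
#' `strict = FALSE`.
#'
#' @param ct_ip_target,ct_input_target Ct values at the target locus.
#' @param ct_ip_ref,ct_input_ref Ct values at the reference locus.
#' @param e_target,e_ref Amplification efficiencies (2 = perfect doubling).
#' @param dilution Input dilution factor (>= 1; 100 means input was 1:100).
#' @param accept Accepted efficiency band.
#' @param strict Reject out-of-band efficiencies (default) or warn only.
#' @return Tibble with the corrected delta-Ct values and `fold`.
#' @export
pfaffl <- function(ct_ip_target, ct_input_target, ct_ip_ref, ct_input_ref,
                   e_target = 2, e_ref = 2, dilution = 1,
                   accept = c(1.9, 2.1), strict = TRUE) {
  cts <- c(ct_ip_target, ct_input_target, ct_ip_ref, ct_input_ref)
  if (length(cts) != 4 || anyNA(cts)) {
    abort("all four Ct values (IP/input x target/reference) are required")
  }
  for (e in c(e_target, e_ref)) {
    if (e < accept[1] || e > accept[2]) {
      msg <- sprintf("efficiency %.3g outside accepted band [%.3g, %.3g]",
                     e, accept[1], accept[2])
      if (strict) abort(paste0(msg, " (set strict = FALSE to override)"))
      warn(msg)
    }
  }
  corr_t <- ct_input_target - log(dilution, base = e_target)
  corr_r <- ct_input_ref - log(dilution, base = e_ref)
  dct_t <- corr_t - ct_ip_target
  dct_r <- corr_r - ct_ip_ref
  tibble(dct_target = dct_t, dct_ref = dct_r,
         fold = e_target^dct_t / e_ref^dct_r)
}
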