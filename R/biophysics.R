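#' Thermal difference spectrum
#'
#' TDS(lambda) = (A_high(lambda) - A_low(lambda)) / max_lambda A_low, the
#' high-temperature (unfolded) spectrum minus the low-temperature (folded)
#' spectrum, normalized by the maximum low-temperature absorbance so
#' different sequences can be compared directly. If the two spectra are on
#' different wavelength grids the high-temperature one is linearly
#' interpolated onto the low-temperature grid.
#'
#' @param low Tibble (`wavelength`, `absorbance`) at low temperature, or a
#'   combined tibble with `wavelength`, `a_low`, `a_high` (e.g. from
#'   [simulate_spectra()]), in which case `high` is ignored.
#' @param high Tibble (`wavelength`, `absorbance`) at high temperature.
#' @return A `tds_result`: tibble (`wavelength`, `tds`) with attribute
#'   `a_max`.
#' @export
tds <- function(low, high = NULL) {
  if (!is.null(low[["a_low"]]) && !is.null(low[["a_high"]])) {
    wl <- low$wavelength; a_lo <- low$a_low; a_hi <- low$a_high
  } else {
    wl <- low$wavelength; a_lo <- low$absorbance
    if (is.null(high)) abort("high-temperature spectrum missing")
    a_hi <- if (length(high$wavelength) == length(wl) &&
                all(high$wavelength == wl)) high$absorbance else
      stats::approx(high$wavelength, high$absorbance, xout = wl)$y
  }
  a_max <- max(a_lo, na.rm = TRUE)
  if (a_max <= 0) abort("maximum low-temperature absorbance must be positive")
  out <- tibble(wavelength = wl, tds = (a_hi - a_lo) / a_max)
  structure(out, a_max = a_max, class = c("tds_result", class(out)))
}

#' Classify a TDS as a G-quadruplex signature
#'
#' A G4 signature shows hyperchromicity below 290 nm and hypochromicity
#' above it, with an isosbestic zero crossing at 290 nm: the classifier
#' requires (i) median TDS > 0 on \[260, pivot - 5\], (ii) median TDS < 0 on
#' \[pivot + 5, 320\] with the smoothed trough below `-min_trough`, and
#' (iii) a downward zero crossing, located by a linear fit of TDS on
#' wavelength over pivot +/- 6 nm, within `tolerance_nm` of the pivot.
#' Medians over flanking bands (rather than a single-wavelength test) make
#' the call robust to grid placement and noise.
#'
#' @param x A `tds_result` (or tibble with `wavelength` and `tds`).
#' @param pivot_nm Isosbestic wavelength (290 nm for G4).
#' @param tolerance_nm Allowed crossing offset from the pivot.
#' @param min_trough Minimum depth of the (smoothed) negative lobe, as a
#'   fraction of the low-temperature maximum.
#' @return List: `is_g4`, `zero_crossing` (nm, NA if none found),
#'   `median_low_band`, `median_high_band`.
#' @export
classify_g4_tds <- function(x, pivot_nm = 290, tolerance_nm = 3,
                            min_trough = 0.02) {
  wl <- x$wavelength; v <- x$tds
  if (min(wl) > pivot_nm || max(wl) < pivot_nm) {
    abort("wavelength grid must span the pivot")
  }
  lo_band <- wl >= 260 & wl <= pivot_nm - 5
  hi_band <- wl >= pivot_nm + 5 & wl <= 320
  med_lo <- stats::median(v[lo_band])
  med_hi <- stats::median(v[hi_band])
  ## smoothed trough just above the pivot
  sm <- stats::runmed(v, k = 5)
  trough_band <- wl >= pivot_nm + 3 & wl <= pivot_nm + 20
  trough <- min(sm[trough_band])
  ## crossing location: average of two shape-agnostic estimators --
  ## (i) root of a local linear fit around the pivot and (ii) linear
  ## interpolation at the smoothed downward sign change nearest the pivot
  win <- abs(wl - pivot_nm) <= 5
  fit <- stats::lm.fit(cbind(1, wl[win] - pivot_nm), v[win])
  slope <- fit$coefficients[2]
  root_lin <- if (is.finite(slope) && slope < 0) {
    pivot_nm - fit$coefficients[1] / slope
  } else NA_real_
  dn <- which(diff(sign(sm)) < 0 & sign(sm[-length(sm)]) > 0)
  root_int <- if (length(dn)) {
    i <- dn[which.min(abs(wl[dn] - pivot_nm))]
    wl[i] - sm[i] * (wl[i + 1] - wl[i]) / (sm[i + 1] - sm[i])
  } else NA_real_
  crossing <- mean(c(root_lin, root_int), na.rm = TRUE)
  if (is.nan(crossing)) crossing <- NA_real_
  is_g4 <- isTRUE(med_lo > 0) && isTRUE(med_hi < 0) &&
    isTRUE(trough < -min_trough) && !is.na(crossing) &&
    abs(crossing - pivot_nm) <= tolerance_nm
  list(is_g4 = is_g4, zero_crossing = unname(crossing),
       median_low_band = med_lo, median_high_band = med_hi,
       trough = trough)
}

#' Fit Langmuir binding kinetics to a stepped-concentration curve
#'
#' Two-stage fit of a label-free biosensor curve under the single-site
#' Langmuir model. For each concentration step at concentration c the
#' relaxation sigma(t) = sigma_inf + (sigma_start - sigma_inf) exp(-k_obs t)
#' is fitted by nonlinear least squares (initialized from the half-rise
#' time); then k_obs is regressed on c by weighted linear least squares:
#' the slope is kon, the intercept koff, and Kd = koff / kon. sigma_max
#' comes from the plateau isotherm sigma_inf(c) = sigma_max c / (c + Kd)
#' with Kd fixed at the kinetic estimate. Steps whose fitted k_obs is not
#' positive are excluded with a warning; at least two usable steps are
#' required. A single-stage global fit of the full piecewise model is
#' available with `method = "global"`.
#'
#' @param curve Tibble with `time` (s), `sigma`, `conc` (nM), e.g. from
#'   [simulate_binding()].
#' @param method `"two_stage"` (default) or `"global"`.
#' @param min_points Minimum points per usable step.
#' @return A `kinetic_fit`: list with `kon` (1/(nM s)), `koff` (1/s),
#'   `kd` (nM), `sigma_max`, `steps` (per-step tibble with `conc`,
#'   `k_obs`, `k_obs_se`, `plateau`), `residual_sd`, `method`.
#' @export
langmuir_fit <- function(curve, method = c("two_stage", "global"),
                         min_points = 10) {
  method <- match.arg(method)
  if (is.unsorted(curve$time, strictly = TRUE)) {
    abort("time must be strictly increasing")
  }
  steps <- split(seq_len(nrow(curve)), cumsum(c(TRUE, diff(curve$conc) != 0)))
  fits <- list()
  for (idx in steps) {
    c_i <- curve$conc[idx[1]]
    if (c_i <= 0 || length(idx) < min_points) next
    tt <- curve$time[idx] - curve$time[idx[1]]
    y <- curve$sigma[idx]
    s0 <- y[1]; s_end <- y[length(y)]
    half <- s0 + (s_end - s0) / 2
    i_half <- which(abs(y - half) == min(abs(y - half)))[1]
    k0 <- log(2) / max(tt[i_half], tt[2])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ s_inf + (s_start - s_inf) * exp(-k * tt),
                        start = list(s_inf = s_end, s_start = s0, k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 200,
                                                             ftol = 1e-14,
                                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                   error = function(e) NA_real_)
    fits[[length(fits) + 1L]] <- tibble(
      conc = c_i, k_obs = unname(co["k"]), k_obs_se = se,
      plateau = unname(co["s_inf"]), n_points = length(idx))
  }
  step_tbl <- bind_rows(fits)
  if (nrow(step_tbl) < 2) abort("need at least 2 usable concentration steps")
  bad <- step_tbl$k_obs <= 0
  if (any(bad)) {
    warn(sprintf("%d step(s) with non-positive fitted k_obs excluded",
                 sum(bad)))
    step_tbl <- step_tbl[!bad, , drop = FALSE]
  }
  if (nrow(step_tbl) < 2) abort("need at least 2 usable concentration steps")
  w <- 1 / step_tbl$k_obs_se^2
  if (any(!is.finite(w))) w <- rep(1, nrow(step_tbl))
  line <- stats::lm(k_obs ~ conc, data = step_tbl, weights = w)
  kon <- unname(stats::coef(line)["conc"])
  koff <- unname(stats::coef(line)["(Intercept)"])
  if (kon <= 0) abort("fitted kon is not positive; not a Langmuir binding series")
  kd <- koff / kon
  ## plateau isotherm with Kd fixed: linear in sigma_max
  xiso <- step_tbl$conc / (step_tbl$conc + kd)
  sigma_max <- sum(step_tbl$plateau * xiso) / sum(xiso^2)
  if (method == "global") {
    g <- tryCatch(global_langmuir(curve, kon, koff, sigma_max),
                  error = function(e) NULL)
    if (!is.null(g)) {
      kon <- g$kon; koff <- g$koff; kd <- koff / kon
      sigma_max <- g$sigma_max
    }
  }
  pred <- predict_langmuir(curve, kon, koff, sigma_max)
  structure(list(kon = kon, koff = koff, kd = kd, sigma_max = sigma_max,
                 steps = step_tbl,
                 residual_sd = stats::sd(curve$sigma - pred),
                 method = method),
            class = "kinetic_fit")
}

predict_langmuir <- function(curve, kon, koff, sigma_max) {
  steps <- split(seq_len(nrow(curve)), cumsum(c(TRUE, diff(curve$conc) != 0)))
  out <- numeric(nrow(curve))
  s0 <- curve$sigma[1]
  kd <- koff / kon
  for (idx in steps) {
    c_i <- curve$conc[idx[1]]
    s_eq <- if (c_i == 0) 0 else sigma_max * c_i / (c_i + kd)
    k <- kon * c_i + koff
    tt <- curve$time[idx] - curve$time[idx[1]]
    out[idx] <- s_eq + (s0 - s_eq) * exp(-k * tt)
    ## propagate the state to the START of the next step, not the last sample
    last <- idx[length(idx)]
    t_next <- if (last < nrow(curve)) curve$time[last + 1] else
      curve$time[last]
    s0 <- s_eq + (s0 - s_eq) * exp(-k * (t_next - curve$time[idx[1]]))
  }
  out
}

global_langmuir <- function(curve, kon0, koff0, smax0) {
  obj <- function(par) {
    curve$sigma - predict_langmuir(curve, par[1], par[2], par[3])
  }
  res <- minpack.lm::nls.lm(par = c(kon0, koff0, smax0), fn = obj,
                            lower = c(1e-12, 1e-12, 1e-12),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  list(kon = res$par[1], koff = res$par[2], sigma_max = res$par[3])
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Langmuir fit (%s): kon = %.4g /(nM s), koff = %.4g /s, Kd = %.4g nM, sigma_max = %.4g (%d steps)\n",
              x$method, x$kon, x$koff, x$kd, x$sigma_max, nrow(x$steps)))
  invisible(x)
}

#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(term = c("kon", "koff", "kd", "sigma_max"),
         estimate = c(x$kon, x$koff, x$kd, x$sigma_max))
}

#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(kon = x$kon, koff = x$koff, kd = x$kd, sigma_max = x$sigma_max,
         n_steps = nrow(x$steps), residual_sd = x$residual_sd)
}

#' @export
augment.kinetic_fit <- function(x, data, ...) {
  mutate(as_tibble(data),
         .fitted = predict_langmuir(data, x$kon, x$koff, x$sigma_max),
         .resid = .data$sigma - .data$.fitted)
}
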