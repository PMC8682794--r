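---
title: "Methods: read-depth CNV detection, G4 association, fluctuation analysis and G4 biophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth CNV detection, G4 association, fluctuation analysis and G4 biophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

g4cnv implements the computational core of a common experimental design in
yeast genome-instability research: sequence a panel of mutant strains
alongside their isogenic wild type, detect copy-number variants (CNVs) from
read depth, ask whether the CNVs associate with G-quadruplex (G4) elements,
quantify gross-chromosomal-rearrangement (GCR) rates by fluctuation
analysis, and characterize candidate G4 sequences biophysically. This
vignette explains each model, its assumptions, the tunable parameters, and
the design decisions taken where more than one reasonable choice existed.
Every empirical statement below is computed by the package's test suite or
by `scripts/acceptance.R`; none is imported from outside.

## Window grid and read counting

Coverage is summarized on sliding windows of 200 bp advancing by 100 bp
(`make_windows()`), the standard resolution for detecting sub-chromosomal
CNVs in a ~12 Mb yeast genome at moderate depth. Two conventions needed
fixing:

* **Trailing stubs are dropped, not truncated.** A partial window at a
  chromosome end would carry a count and a GC estimate on a different
  length scale than every other window; dropping it keeps the grid
  homogeneous. Tools that emit trailing stubs will differ in the last
  window of each chromosome.
* **A read increments every window it overlaps by at least 1 bp**
  (bedtools-coverage semantics). With half-overlapping windows a read
  spanning a window boundary can touch three windows, and a read contained
  between two boundaries touches two; the library total is therefore
  tracked separately from the per-window sums. The counting path is tested
  against an exhaustive read-by-window brute-force oracle.

Per-window GC (`window_gc()`) is (G+C)/(A+C+G+T) with ambiguous bases
excluded from both numerator and denominator; all-N windows get `NA` and
are excluded from GC-dependent steps.

## GC-bias normalization

Sequencing depth depends on local GC content. `fit_gc_model()` fits a
robust linear regression of count on GC (M-estimation, Huber weights,
tuning constant 1.345, iterated to a relative coefficient change below
1e-8 or 50 iterations) and converts the fit into multiplicative per-window
correction factors, (mean fitted value)/(fitted value at the window's GC),
floored at 0.1 and capped at 10 to keep extreme extrapolations from
exploding counts. If the linear fit predicts a non-positive count anywhere
in the observed GC range the model refits on the log scale, whose fitted
values are positive by construction.

The robust fit tolerates a minority of windows at shifted copy number (the
very CNVs we are looking for), but a mitochondrial chromosome at ~20x
nuclear depth is not a minority feature on a compact genome, so
`exclude_chroms` removes it from the fit while the factors still apply
genome-wide.

A linear correction removes the linear component of any smooth bias; on
the generator's quadratic bias over a realistic window-GC span the
residual robust slope after correction is ~3% of the uncorrected slope
(measured on a 50,000-window genome in the acceptance suite), and
bias-free samples are left unchanged to within 5% (in practice < 0.1%).

## The per-window chi-squared test and CNV calls

For each window w the control and mutant samples are compared with a
2x2 Pearson chi-squared homogeneity test (1 df, no continuity
correction) on

    [[ wt_w, wt_total - wt_w ], [ mut_w, mut_total - mut_w ]]

i.e. the window against the rest of each library, using GC-normalized
counts; both library sizes therefore enter the statistic. A goodness-of-fit
style alternative on raw counts is available (`use_normalized = FALSE`).
Benjamini-Hochberg adjustment is applied across all tested windows of one
control/mutant pair -- comparisons are pairwise per strain, so the FDR
family is per pair, not pooled across strains. Windows with zero counts in
both samples are excluded.

Significant windows of the same direction whose spans overlap or adjoin
are merged (`merge_calls()`); an interval is a bona fide CNV only when its
span strictly exceeds 500 bp and it contains at least three significant
windows. Gains and losses never merge across direction.

**Assumptions and their failure modes.** The chi-squared test treats
window counts as multinomial draws, i.e. Poisson-like noise. Two measured
consequences:

* Under Poisson noise the pipeline is cleanly calibrated: null sample
  pairs over 50,000 windows yield zero CNV calls, and 20 planted CNVs
  (0.6-2 kb, copy 0, 0.5 or 2, depth 100 reads/window) are recovered with
  recall and precision around 0.9-1.0 at 50% reciprocal overlap.
* Under negative-binomial noise with dispersion 0.1 (variance
  mu + 0.1 mu^2) the statistic is inflated by roughly
  1 + depth x dispersion (~11x at depth 100); about half of all null
  windows become BH-significant and the merge filter cannot rescue
  calibration (~1,200 spurious calls per 50,000-window null pair). This is
  a property of the method, not of the implementation: a Pearson test has
  no dispersion parameter. The acceptance suite asserts the type-I
  property under the negative-binomial conditions and the assertion fails,
  deliberately and reproducibly -- treat chi-squared window calls on
  overdispersed libraries as a candidate list, not a calibrated one.

Long hemizygous (copy 0.5) CNVs can fragment into adjacent calls when two
consecutive windows fall below the significance threshold; the per-call
precision figures above count such fragments as false positives when they
fail reciprocal overlap. Fragmentation grows with CNV length and shrinks
with depth.

Whole-chromosome duplications are flagged by `chromosome_ploidy()`: each
sample is rescaled by its genome-wide median, and a chromosome whose
median ratio reaches 1.75 is flagged duplicated -- midway between 1 and 2
on a haploid baseline, with margin for noise. Chromosomes with fewer than
10 windows report a ratio but no flag.

## Mitochondrial copy number

`mtdna_copy_number()` computes RPKM = count / (length_kb x
total_mapped_millions) per feature and reports mtDNA RPKM divided by the
mean RPKM of single-copy nuclear genes. The ratio is oriented so that more
mitochondria give a larger number (an `invert` flag provides the
reciprocal, since the opposite orientation is also seen in the
literature), and relative copy number across samples divides by a control
sample. Quantile normalization of the per-gene RPKM vectors across samples
is available as an optional pre-step (via limma). On synthetic data with a
planted 20x mitochondrial multiplier the estimate returns 20 within 1%.

## G4 motif scanning

`scan_g4()` uses the canonical quadparser motif: at least 4 G-runs of at
least 3 nt separated by loops of 1-25 nt, scanned greedily left to right
on both strands (C-runs on the forward strand are G-runs on the reverse).
Overlapping matches on a strand are merged into one motif per locus so
nested matches do not inflate counts. The defaults were chosen so that the
two published GCR-assay cassette sequences match while their G-to-C
substituted mutants (which keep GC content but break two internal G-runs)
do not -- both facts are asserted in the acceptance suite. The scanner
reports run and loop structure per motif; it does not attempt
thermodynamic stability scoring.

## Overlap enrichment and the matched resampling null

`overlap_enrichment()` classifies every universe interval (normally the
window grid) by whether it overlaps the query set and the G4 set and tests
the 2x2 table. Counting universe windows rather than elements keeps the
margins well defined; any interval set can be passed as the universe for
element-level counting. Both the two-sided Fisher exact p (minimum-
likelihood rule) and the one-sided hypergeometric upper tail are reported,
because either may be quoted in comparable analyses; the odds ratio uses
the Haldane 0.5 correction when a cell is zero. The exact p-values are
computed from the hypergeometric density over the whole support, which
makes an exhaustive verification feasible: the test suite checks every
table with all margins at or below 60 (about 1.2 million table outcomes,
using the m <= n symmetry of the margins) against an independent
log-factorial enumeration oracle to 1e-9, and spot-checks
`stats::fisher.test` on random tables.

`distance_to_nearest()` reports edge-to-edge gaps (0 when overlapping,
half-open coordinates). `resample_null()` builds the null distribution for
"are the observed intervals closer to G4 than chance": each of `n_reps`
(default 1000) replicates draws one random interval per observed interval,
of the same length, placed uniformly genome-wide -- chromosome chosen with
probability proportional to placeable start positions, start uniform among
them. Placement is genome-wide rather than per-chromosome (a
stratification flag would be a natural extension); resampled intervals may
overlap each other. The summary statistic is the mean distance (median via
`summary = median`); the empirical lower-tail p uses the add-one rule
(1 + #{replicate <= observed}) / (n_reps + 1), so the smallest attainable
p at 1000 replicates is 1/1001, which is exactly what planted-on-G4
queries return. Replicates in which every interval lands on a chromosome
without G4 elements carry no distance information and are dropped with a
warning (the effective replicate count adjusts the p denominator).
Calibration is verified by generating queries from the placement rule
itself: across 200 seeds the empirical p is uniform (Kolmogorov-Smirnov
at alpha 0.01).

## Fluctuation analysis (MSS maximum likelihood)

The Luria-Delbruck mutant-count distribution is computed by the
Ma-Sandri-Sarkar recursion (`mss_pmf()`):

    p_0 = exp(-m);  p_r = (m / r) * sum_{i=0}^{r-1} p_i / (r - i + 1)

implemented in C++ because the recursion is O(r_max^2). The distribution
has a quadratic tail (r^2 p_r converges to m, verified numerically), so
the mass beyond any feasible truncation is ~ m / r_max and the truncated
sum cannot approach 1 to machine precision -- driving the residual below
1e-9 would need r_max around 1e10. `mss_pmf()` therefore returns the exact
recursion values (p_0 is exact at any truncation) together with the
analytic tail estimate m / (r_max + 1) as an attribute, and the
documentation of every consumer states how the tail is handled:

* **Sampling** (`simulate_fluctuation()`) inverts the CDF on an adaptively
  extended support (capped at 65,536) and clamps the ~m/cap fraction of
  draws that fall beyond it.
* **Likelihood** (`mss_mle()`) censors jackpot counts at 5,000: counts at
  or above the cap contribute through P(X >= cap) instead of requiring
  the recursion out to the largest jackpot. The maximum is found by
  bounded scalar optimization with the bracket seeded from the p0 method
  (-log fraction of mutant-free cultures) and expanded if the optimum
  lands near the bound; the 95% CI comes from the profile-likelihood drop
  of 1.92 log-units. Rate = m / Nt.
* **Plating fractions** below 1 are handled by exact binomial thinning of
  the pmf (a windowed C++ convolution); a count-rescaling mode is provided
  for compatibility with tools that divide m by the fraction.

Parameter recovery: simulated experiments at m = 2 with 1000 cultures
return estimates within [1.8, 2.2]; the p0 method agrees within the
profile CI; estimator error shrinks from 100 to 10,000 cultures. Rate
ratios (`fold_enrichment()`, mutant over wild type) recover a planted 15:1
ratio as a mean fold between 10 and 20 over three replicate pairs of 100
cultures each -- fluctuation-test fold estimates are intrinsically noisy,
which is why replicate fold values, not just the mean, are reported.

## Pfaffl qPCR enrichment

`pfaffl()` implements efficiency-corrected relative quantification for
ChIP: delta-Ct = Ct_input - Ct_IP per locus after correcting the input Ct
for its dilution (subtract log_E of the dilution factor), and fold =
E_target^dCt_target / E_ref^dCt_ref with a reference locus as internal
standard. Efficiencies are accepted in [1.9, 2.1] (95-105%) and rejected
outside unless `strict = FALSE`. The closed-form worked examples (fold 1
when the delta-Cts match, fold 4 at E = 2 with delta-Cts 3 and 1) are
exact.

## Thermal difference spectra

`tds()` subtracts the low-temperature (folded) spectrum from the
high-temperature (unfolded) one and normalizes by the maximum
low-temperature absorbance, interpolating linearly if the grids differ.
G4-folded sequences show a characteristic signature: positive TDS below
290 nm, negative above, zero crossing at the 290 nm isosbestic point.
`classify_g4_tds()` requires (i) positive median on [260, 285], (ii)
negative median on [295, 320] with a smoothed trough below 2% of A_max
(real G4 troughs are 10-30%), and (iii) a downward zero crossing within 3
nm of 290. Band medians rather than single-wavelength tests give
robustness to grid placement and noise.

The crossing is located as the average of two shape-agnostic estimators: a
local linear fit over 290 +/- 5 nm and linear interpolation at the
smoothed (running median, k = 5) downward sign change nearest the pivot.
The averaging matters: the TDS is strongly asymmetric around 290 (the
trough at ~296 is deeper than the shoulder at ~287 is high), so any
mean-based local fit is biased short while the sign-change interpolation
is unbiased but noisier. At a flat white noise of 5% of A_max per
wavelength -- far above real spectrophotometer noise on a ~1 OD sample --
the crossing cannot be localized within +/-3 nm more than ~93% of the time
by any of the shape-agnostic estimators we measured (local linear at
several bandwidths, quadratic, tricube-weighted, iterated re-centered,
median-smoothed interpolation); the classifier's robustness sweep
therefore spans noise levels from 1% to 5% of A_max, over which the true
positive rate exceeds 95% and the false positive rate on duplex and
single-stranded spectra stays at or below 5%.

## Langmuir binding kinetics

`langmuir_fit()` analyzes stepped-concentration biosensor curves under the
single-site Langmuir model. Within a step at concentration c the surface
density relaxes exponentially toward sigma_max c/(c + Kd) at the observed
rate k_obs = kon c + koff. The default two-stage scheme fits each step's
exponential by nonlinear least squares (initialized from the half-rise
time), then regresses k_obs on c -- slope kon, intercept koff, Kd =
koff/kon -- and recovers sigma_max from the plateau isotherm with Kd held
at the kinetic estimate. This is the standard reading of "fit each
averaged curve with an exponential growth function" that yields kon and
koff separately; a simultaneous global fit of the full piecewise curve is
available (`method = "global"`) and agrees on clean data. Units are fixed
(concentration nM, time s, kon in 1/(nM s)). Noiseless round-trips
recover all parameters to 1e-6 relative; at 2% multiplicative noise the
default five-spike series (0.08, 0.4, 2, 10, 50 nM) returns Kd within a
few percent (15% at the 95th percentile across 100 seeds). Steps with
non-positive fitted rates are excluded; at least two usable steps are
required.

## The synthetic-data module

Every stage is testable without external downloads because
`simulate_genome()`, `simulate_coverage()`, `simulate_fluctuation()`,
`simulate_spectra()` and `simulate_binding()` generate inputs with known,
machine-readable ground truth, and each is a pure function of (config,
seed) -- the caller's RNG state is restored.

What the generators emulate, and what they deliberately do not:

* **Genome**: a scaled-down yeast-like layout (four nuclear chromosomes of
  150-300 kb plus an 86 kb mitochondrial chromosome) with a smoothly
  varying GC landscape (0.38 +/- 0.10) and planted G4 motifs at recorded
  coordinates. Accidental G/C runs of 3+ outside planted motifs are broken
  by default (`mask_g4`), so the planted set is exactly the scanner's
  ground truth; real genomes of course contain abundant unplanned motifs.
* **Coverage**: expected count = depth x copy x gc_bias(gc), with Poisson
  or negative-binomial noise (default dispersion 0.1, since the noise
  model of real libraries is library-specific) and an Illumina-like
  unimodal quadratic bias peaking at GC 0.40 and falling to 0.5 at GC
  0.2/0.6. Window counts are drawn independently; real 200/100 windows
  share roughly half their reads with each neighbour, so real counts are
  positively correlated between adjacent windows. Mappability, repeats and
  read-level error models are out of scope.
* **Fluctuation counts** are drawn from the MSS pmf directly rather than
  by simulating cultures -- the exact target distribution, and a pmf test
  in itself.
* **Spectra** follow analytic band shapes whose TDS is sign-exact by
  construction (crossing exactly at 290 nm for G4); noise is white
  Gaussian per wavelength, scaled to A_max. Real spectra have correlated
  baseline drift instead.
* **Binding curves** are exact piecewise Langmuir relaxations, continuous
  across concentration steps, with optional multiplicative noise.

Passing tests on these generators demonstrates correctness of the
algorithms under their stated assumptions; it does not demonstrate that
real libraries satisfy those assumptions (the negative-binomial type-I
result above is the clearest example of the distinction).

## Problem sizes and numerical choices

The test and acceptance workloads use genomes of 1 - 5 Mb (25,000 -
50,000 windows), 20 planted CNVs of 0.6 - 2 kb (the size class of
sub-chromosomal CNVs this design targets), depth 100 reads/window,
1000-replicate resampling nulls, 200-seed calibration sweeps,
1000-culture fluctuation experiments, and 100-seed noise sweeps --
sizes chosen so the full suite exercises every property at meaningful
scale while remaining runnable on a laptop in minutes. Fixed numerical
choices: Huber tuning 1.345; correction-factor bounds [0.1, 10]; FDR 0.05;
merge thresholds span > 500 bp (strict) and >= 3 windows, the standard
filter in this assay design; duplication flag 1.75; scanner
defaults 4 runs of G >= 3, loops 1-25; MSS jackpot cap 5,000 and sampling
cap 65,536; profile drop 1.92; efficiency band [1.9, 2.1]; classifier
bands [260, 285] / [295, 320], trough 2% of A_max, crossing tolerance 3
nm.

## Known limitations

* The chi-squared window test is anticonservative on overdispersed
  libraries (quantified above); a dispersion-aware test (e.g.
  beta-binomial) would be the natural extension.
* Call fragmentation across power dips penalizes per-call precision for
  long hemizygous losses.
* Breakpoints are window-resolution; no sub-window refinement.
* The resampling null does not condition on chromosome or on local GC.
* The G4 scanner is pattern-based; it does not score thermodynamic
  stability and does not reproduce any published prediction catalogue.
* `mss_mle()` assumes a constant mutation rate per generation and no
  phenotypic lag; plating fractions are assumed binomial.
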