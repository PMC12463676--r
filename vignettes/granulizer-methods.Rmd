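---
title: "granulizer: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{granulizer: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(granulizer)
```

`granulizer` implements the quantitative stages of a small-molecule
stress-granule study as one coherent toolkit. This vignette is the
package's account of the science behind each stage: the models and their
assumptions, the parameters that matter, the numerical choices, what the
synthetic-data generators do and do not emulate, and where the design was
genuinely open.

## Thermal proteome profiling scores

TPP heats aliquots of treated and control cells across a temperature
gradient and quantifies the remaining soluble protein by multiplexed
mass spectrometry. `granulizer` consumes the resulting protein ×
temperature × condition intensity array (`melt_curve_matrix`, default
grid 37.0–66.3 °C in ten steps) and deliberately avoids melting-curve
fitting: the scores are sums and means of per-temperature log2 fold
changes, which are robust to proteins whose soluble fraction never
reaches a clean sigmoid.

* The **abundance score** is the mean log2 fold change at the two lowest
  temperatures, where essentially nothing has melted; it captures
  expression/solubility changes independent of thermal stability.
* The **thermal stability score** subtracts the abundance score from
  every temperature's log2 fold change and sums the residuals. A
  uniform fold change therefore scores 0 (shift invariance), and
  negating the fold changes negates the score (antisymmetry) — both are
  enforced as exact (1e-12) properties in the test suite.
* Zero or missing intensities leave the fold change undefined at that
  temperature; a stability score requires `min_points` quantified
  temperatures (default 10, the complete standard grid) because the sum
  is not comparable across very different grid coverage.

Scores are z-transformed per contrast (mean/sd, sample sd with the n−1
denominator). Whether standardization should pool across contrasts is
open; per-contrast is the default because contrasts can differ in global
dispersion, and each contrast is analyzed independently.

**Significance.** The published workflow runs the scores through a
moderated linear-model test and an FDR estimator; neither step is
reproducible exactly from a methods description, so `granulizer` owns the
contract instead: the bulk of the z distribution is treated as the null,
its center and scale estimated robustly (median and MAD) so that a
minority of true effects cannot inflate the null; each protein carries a
precision weight proportional to its number of quantified temperatures,
entering as an inverse scaling of its null variance. At the score level
there are no per-protein replicate variances left to shrink, so the
pooled robust scale is used for every protein — the fully shrunk limit of
an empirical-Bayes variance model. Two-sided p-values follow from the
scaled normal null; FDR is Benjamini–Hochberg by default, with a
local-fdr alternative (two-groups model, half-normal null refit on the
central 90 % of the distribution, kernel density for the marginal,
monotonized away from the center). The classification rule is the
conventional double cutoff, |z| > 1.5 and FDR < 0.05.

A simulation with no planted effect classifies ≤ 5 % of proteins, and a
+2 °C melting shift at 5 % intensity noise gives positive stability
scores in ≥ 95 % of affected proteins — both checked in the suite at
1,000 proteins, a size chosen so the whole TPP test file runs in seconds
while leaving the empirical null plenty to estimate from.

## NMR uptake and condensate partitioning

All relations here are closed-form mass conservation; the package's job
is to make the unit conventions impossible to get wrong. Internally
everything is SI-coherent — lengths m, areas m², cell volumes m³, liquid
volumes L, concentrations mol/L — and the single cross-unit step (a cell
volume in m³ meeting a liquid volume in L) is explicit in one place.

* Fractional uptake U = 1 − S₊cells/S₋cells. Noise can push S₊ slightly
  above S₋; overshoot up to 2 % (configurable) clips to U = 0, more is a
  hard measurement-inconsistency error rather than silent clipping.
* C_out = (1−U)·c_add·V_add/V_out and C_cell = U·c_add·V_add/(V₁·N_cell),
  with V_out = V_add by default (total cell volume ≪ medium volume), but
  V_out remains a separate argument.
* The membrane-binding bound R = A_L·N_A·U·c_add·V_add/(A₁·N_cell) uses
  the 2019 exact Avogadro constant and a 0.5 nm² lipid footprint.
* The pellet of condensate in a hemispherical tube bottom is a spherical
  cap, V = π/3·r³(2+cos θ)(1−cos θ)², θ = asin(a/r); the implementation
  is validated against numerical quadrature of the solid of revolution
  at 1e-9 relative tolerance, is strictly increasing in a, and reaches
  the hemisphere (2/3)πr³ at a = r.
* PC = (V_cond + V_added)/(SF·V_cond) and the phase concentrations
  conserve mass to 1e-9 relative on randomized valid inputs (a suite
  property), with PC·[L]_dil = [L]_cond an exact round-trip.

These formulas assume the integrated amide-proton signal is proportional
to concentration, which holds at low temperature and moderate pH (the
measurement regime); the package documents but does not model
chemical-exchange corrections.

## Image quantification

Fields are plain numeric matrices (one channel each); EBImage provides
filtering, Otsu thresholding and connected-component labelling.

* **Nuclei**: Gaussian blur with σ = 5 px, threshold, label, discard
  regions under 50 px. "5-pixel blur" is read as σ = 5 px (not kernel
  width) — a stated convention, as is the unsharp reading below.
* **Granules**: unsharp enhancement (img − w·blur)/(1−w) with σ = 10 px,
  w = 0.9, threshold, label, then remove every component that touches
  the nuclei mask — the granule mask never overlaps nuclei by
  construction. Minimum area 2 px suppresses single-pixel noise.
* Thresholds default to Otsu on the min–max-normalized image, which
  makes counts invariant to linear intensity rescaling (a suite
  property); a fixed numeric threshold is available where a screen
  demands one. Blank (constant) images give zero labels, not an error.
* Per-field statistics: granules per cell n_granules/n_nuclei (undefined
  and excluded when a field has no nuclei), nuclear partition
  p = a/(1−a) from the nuclear fraction a of total reporter signal
  (per field, the stated readout; a per-cell variant would need
  cell-boundary segmentation, which the package does not attempt), and
  percent of cells with ≥ k granules (k = 3 by default), monotone
  non-increasing in k.
* Compartment partition coefficients divide a compartment's mean
  labelled-compound intensity by the mean over the cytoplasm excluding
  granules and mitochondria; masks must be disjoint, empty compartments
  yield missing values.

Only 2-D fields are handled; z-stacks should be maximum-projected before
input. Segmentation quality on real, noisy, confluent fields is bounded
by these simple operators — the tests establish correctness of the
operators, not state-of-the-art segmentation.

## Screen scoring and dose–response

Each plate is scored against its own DMSO controls: per feature,
z = (x − μ)/σ with control mean and sample sd; constant control features
are dropped with a warning. The z-vector is combined into a Mahalanobis
distance D = √(zᵀS⁻¹z) with S the covariance of the control wells'
z-vectors. Screening plates have few controls (~32) relative to the
typical ~15 features, so the plain inverse is unstable; S is shrunk
toward its diagonal with a Ledoit–Wolf-style intensity estimated from
the controls (Schäfer–Strimmer form), and the distance is computed by
Cholesky triangular solves. Covariance is per plate — pooling across
plates is possible in principle but couples plates through batch
effects, so it is not the default. The suite checks D against an
explicit matrix-inverse oracle at 1e-10, its invariance to per-feature
rescaling, and that on a synthetic 1,536-well screen (4 × 384 wells,
32 controls each, 20 hits shifted 2–4 control-sd per feature with random
signs) ≥ 90 % of planted hits rank in the top 5 %.

In vitro plate reads drift as condensates sediment; values are
referenced to the linear interpolant between start- and end-of-row
control reads (divide by default, subtract optionally); a missing
flanking control leaves the row uncorrected and flagged.

"Monotonic dose dependence" is operationalized as |Spearman ρ| ≥ 0.8
between concentration and response (direction selectable), since the
underlying criterion is qualitative; rank correlation is insensitive to
the response scale.

**EC50.** The sigmoid is the four-parameter logistic — the standard
reading of a "Rodbard" curve — fitted on the log-concentration axis by
Levenberg–Marquardt least squares with a multistart grid (slope in
{−2, −1, 1, 2} crossed with EC50 at the quartiles of the tested range);
the best converged start wins, with ties broken toward the first found
(starts differing by < 1e-12 relative RSS are treated as equal). The
parameterization is canonicalized so the slope is positive and `top` is
the low-dose asymptote, matching granule counts that fall with dose.
Degenerate inputs are flagged, never silently patched: responses with no
usable dynamic range (range below 1e-6 of scale) return a
`flat_response` flag without invoking the optimizer; an EC50 outside
[min conc/10, max conc·10] is flagged `ec50_outside_range`;
non-convergence of every start is flagged. Noiseless synthetic curves
round-trip the EC50 to 1e-6 relative; at 10 % multiplicative noise on a
12-point series the EC50 is recovered within 25 % of truth in ≥ 90 % of
200 seeded replicates (an acceptance-suite Monte-Carlo).

## IDR calling and composition enrichment

A residue is consensus-disordered when strictly more than 75 % of the
predictors call it disordered, and an IDR is a maximal run of strictly
more than ten such residues. Both inequalities follow the stated rule
literally and are configurable, because upstream databases do not
document whether their own convention is strict; the boundary behavior
(3 of 4 predictors is not enough; a run of 10 is not an IDR, 11 is) is
pinned by tests, and interval calling is verified against a naive
per-residue scan oracle on random profiles. Intervals are 1-based
inclusive in all outputs, stated in the file header.

IDR proportions are compared between stability classes with a two-sample
rank-sum (Wilcoxon) test and Holm adjustment. A signed-rank test is
sometimes quoted for such comparisons, but the groups here are unpaired
and of very different sizes (tens vs thousands), so a paired test is not
applicable; the rank-sum test is the defensible choice and classes with
fewer than three members are skipped and flagged.

Composition enrichment of a group of IDR sequences against a background
is the relative frequency difference (f_group − f_bg)/f_bg per amino
acid on pooled residue counts: 0 is background-like, −1 complete
depletion, +1 a doubling. The reconstruction identity
(1 + score)·f_bg = f_group holds to 1e-12. Dispersion is a bootstrap
standard deviation over proteins (both sets resampled) — chosen over an
across-protein sd because proteins contribute very different residue
counts; significance is an unpaired t-test on per-protein frequencies
with Bonferroni adjustment across the 20 amino acids. Amino acids
absent from the background have no defined score and are flagged.

## Synthetic data

Every generator is a pure function of its arguments and a master seed,
and draws from its own RNG stream derived from (seed, generator name):
adding a generator or reordering calls never changes another's output,
and each generator returns a ground-truth record alongside the data.

* `gen_tpp` draws melting temperatures uniformly on 45–55 °C (a range
  resembling published human meltome studies), melt slope 2 °C, 5 %
  non-denaturable plateau, log-normal intensity noise of given CV
  (mean 1), and plants melting-point and/or abundance shifts in disjoint
  subsets. What it does not emulate: missing-at-higher-temperature
  censoring patterns of real TMT data, correlated noise across
  temperatures within a TMT run, or co-melting protein complexes.
* `gen_field_image` packs Gaussian-profile nuclei without overlap
  (bounded rejection sampling; an infeasible request errors rather than
  looping), plants bright puncta in the cytoplasm and optionally inside
  nuclei, and adds Gaussian read noise. It does not emulate uneven
  illumination, cell-to-cell intensity variation, touching nuclei or
  out-of-focus light — so passing counts prove operator correctness,
  not robustness to those artifacts.
* `gen_plate` draws control and background wells from a multivariate
  normal with AR(1) feature correlation (ρ = 0.5) and shifts hit wells
  by 2–4 control-sd per feature with random signs. Real screens add
  spatial plate effects (edge wells, gradients) that are not simulated.
* `gen_dose_response` is the 4PL forward model with multiplicative
  log-normal noise; `gen_disorder` plants one IDR per protein (longer in
  the stabilized class), predictor calls with a given within-IDR
  agreement and out-of-IDR false-call rate, and sequences whose
  stabilized-class IDRs are enriched in R/Y/F by a configurable factor
  over an average proteome background.

## Problem sizes and runtime

The suite runs the TPP recovery at 300–1,000 proteins, the screen at
1,536 wells, the EC50 Monte-Carlo at 50 (unit) and 200 (acceptance)
replicates, and image fields at 256 × 256 px — sizes picked so the full
suite completes in well under a minute on one core while keeping every
statistical check adequately powered.

## Known limitations

* The significance machinery reproduces the decision surface (|z| and
  FDR cutoffs) of the published moderated-test workflow, not its exact
  per-protein p-values, which depend on internals that a methods
  description does not pin down.
* The condensate partition coefficient is reported per measurement; no
  pooling across replicate experiments is built in.
* Composition enrichment assumes the 20-letter alphabet; non-standard
  residues are reported but excluded from frequencies.
* The reference methionine-count checks for canonical human SFPQ and
  SRSF1 need those public sequences as extdata; they are not
  redistributed with the package.
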