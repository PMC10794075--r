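---
title: "Models, fixtures and numerical choices in ftirsugars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, fixtures and numerical choices in ftirsugars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirsugars)
```

This vignette is the package's own account of the science it implements:
the quantification models and their assumptions, what the synthetic
fixture generator does and does not emulate, and the numerical and design
choices that were genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The quantification problem

Citrus juices enriched in fructo-oligosaccharides — either by
β-fructosyltransferase treatment, which transfers fructosyl units from
sucrose to growing chains while releasing glucose, or by direct addition
of FOS preparations — contain up to six carbohydrates with very similar
structures: Glc, Fru, Suc and the oligomers GF2 (1-kestose), GF3
(nystose) and GF4 (fructofuranosyl nystose). All absorb strongly in the
mid-infrared fingerprint region, 1250–900 cm⁻¹, through C–O and C–C
stretching modes; the oligomers share most of their functional groups and
differ only in subtle intensity ratios. The package quantifies each sugar
in g/L from ATR absorbance spectra sampled every 2 cm⁻¹.

## Simultaneous-equation model

Spectral additivity and the Bouguer–Beer law give, at each wavenumber ν,

$$A(\nu) = A_w(\nu) + \sum_{i=1}^{K} k_i(\nu)\, c_i,$$

where $A_w$ is the pure-water absorbance and $k_i$ the absorptivity of
sugar $i$ per g/L. Slopes are calibrated per component and wavenumber
from single-sugar standards by least squares through the *fixed* water
intercept, $\hat k = \sum_j c_j (a_j - A_w) / \sum_j c_j^2$, so a single
standard solution determines the slope exactly — matching how standards
at one concentration level (~120 g/L for mono-/disaccharides, ~80 g/L
for the oligomers) are typically prepared. Choosing exactly $m = K$
wavenumbers gives a square system $\mathbf K c = a - a_w$ solved
directly. Key behavioural choices:

* **Raw solutions are reported.** Negative concentrations are possible
  and deliberately not clamped (an option exists), because error metrics
  must see the solver output.
* **Singularity is an error, not noise.** Systems whose slope-matrix
  condition number (exact SVD-based) exceeds a cap (default 10¹⁰) are
  rejected with the offending wavenumbers named.
* **Subset search is exhaustive.** All $\binom{n}{K}$ subsets of the
  candidate list are scored by the mean per-component RMSE of their
  predictions; ties break towards lower condition number, then
  lexicographic wavenumber order, making the search invariant to
  candidate ordering. Heuristic optimizers (GA, simulated annealing) are
  intentionally out of scope: the point of this workflow is
  assignment-driven, interpretable selection.
* **Candidates come from peak extraction**, the union of per-component
  peak sets taken round-robin by prominence (~18 by default), since peak
  positions of the measured standards are the natural candidate pool.

On noiseless Beer–Lambert data every nonsingular subset is exact to
machine precision — the test suite asserts this — so any SE failure in
realistic conditions is attributable to noise, overlap and derivative
effects, which the suite probes with a noise-monotonicity property.

## Savitzky–Golay second derivative

Derivative spectroscopy suppresses baseline shifts and sharpens the flat,
overlapping oligomer bands; absorbance maxima become derivative minima.
The implementation fits a polynomial of degree `polyorder` to each
17-point window (the acquisition-matched default) and reports the fitted
second derivative at the window center, scaled by the grid step so units
are AU per (cm⁻¹)². Choices:

* **Polynomial order defaults to 3.** The window length alone does not
  fix the order; for symmetric windows orders 2 and 3 give identical
  second derivatives (asserted in the tests), so the choice is inert at
  the default and exposed as a parameter.
* **No padding is invented.** The derivative exists only where the full
  window fits; the returned spectrum lives on a grid trimmed by 8 points
  (16 cm⁻¹) per side. Because the derivative is always taken on the full
  4000–400 cm⁻¹ acquisition grid *before* cropping, and the fingerprint
  region is over 350 cm⁻¹ from either end, edge handling can never touch
  the modelled variables — `prepare_matrix()` enforces this order of
  operations.
* **No sign flip or rescaling.** Models consume derivative values as-is;
  the water intercept of the derivative-mode SE method is simply the
  derivative of the water spectrum.

## PLS-1 and cross-validation

The regression core is NIPALS PLS-1 on mean-centered data (no
unit-variance scaling, the usual choice for spectra where a common unit
makes variance scaling noise-amplifying; autoscaling is a flag). Factors
are extracted sequentially with deflation of both X and y; the
coefficient vector $b_a = W_a (P_a^\top W_a)^{-1} q_a$ is precomputed for
every factor count so cross-validation can evaluate all counts from one
fit. Extraction halts early when the deflated X is numerically exhausted
(residual norm < 10⁻¹²), truncating the factor count — this is what makes
noiseless rank-deficient fixtures behave exactly.

Cross-validation partitions samples into groups whose sizes differ by at
most one (the first `n mod g` groups take the extra sample), with a
seeded random assignment; leave-one-out is deterministic. One *global*
factor count is chosen by minimum CV RMSE over 1..10 (the cap reflects
the 2–7 factors typical for these models), with ties broken towards
fewer factors. R² is computed on the pooled held-out predictions,
consistent with pairing R² and CV RMSE. The selection harness reuses a
single fold assignment across the A/B/C patterns of all components so
comparisons are paired.

The A/B/C patterns formalize assignment-driven variable reduction: A is
the full 176-point region, B the target sugar's own peaks, C the union of
all components' peaks, with provenance tags recording which component
contributed each wavenumber. B ⊆ C ⊆ A holds by construction and is
asserted as a property.

Peak extraction itself uses a relative-prominence threshold (default 2 %
of the region's largest baseline-subtracted deviation — invariant to
constant offsets), a 6 cm⁻¹ minimum separation thinned greedily by
descending prominence, and an optional count cap. These defaults
reproduce the order of magnitude of assignment-driven peak counts
(roughly 6–11 per sugar on the default library) without being tuned to
match any exact count; exact counts are a property of real measured
spectra and are deliberately not asserted.

## What the synthetic fixtures emulate

The generator stands in for undeposited measured spectra; its defaults
*are* the study conditions and are not adjusted per experiment.

* **Band libraries.** Each sugar is a sum of Gaussian bands at the
  published assignment centers plus a few minor unnamed bands for
  realistic complexity. The strongest band is scaled to 0.002 AU per
  g/L (≈ 0.2 AU at 100 g/L, a typical ATR magnitude; no absolute
  intensities are published). GF2/GF3/GF4 share the five FOS centers
  with height ratios differing by ~10–25 % and slightly different
  widths, plus two small oligomer-specific bands each (GF2 1118/966,
  GF3 1090/952, GF4 1160/1014 cm⁻¹) emulating the degree-of-polymerization
  differences that make the real oligomers distinguishable. GF4's main
  width is 12 cm⁻¹: widths much above this merge the 1060/1034 pair and
  would violate the requirement that every assigned center be a
  detectable maximum of its pure profile. Water is a sum of very broad
  Gaussians (O–H stretch, association band, bending, libration
  shoulder).
* **Noise model.** iid Gaussian noise of sd 5×10⁻⁴ AU plus a linear
  baseline tilt of amplitude 10⁻³ AU with a random per-spectrum slope —
  magnitudes chosen once so that model accuracy lands in the regime
  reported for real juice spectra. All generation is seeded and
  bit-for-bit reproducible; seeds change only the noise.
* **Kinetics.** The transfructosylation chain is integrated as
  irreversible mass action (RK4, fixed step 0.01 h; enzyme dose is a
  linear multiplier on all rates). The anhydro molar masses
  (Glc/Fru 180.16, Suc 342.30, GF2 504.44, GF3 666.58, GF4 828.72 g/mol)
  make every reaction conserve mass exactly, so the glucosyl-unit mole
  count is a strict invariant checked against an independent stiff
  integrator. Rate constants were calibrated once, by unweighted least
  squares, to the reference endpoint of a 9000 U/L, 6 h treatment
  (Suc 41.9 → 11.1, GF2 → 12.1, GF3 → 2.3 g/L). That endpoint is not
  exactly reachable: its sucrose loss exceeds what the product masses
  account for (the reference concentrations sit on an unclear dilution
  basis), so the calibrated chain lands at Suc 13.2, GF2 14.9, GF3 5.5
  g/L and, at higher doses, GF2/GF3 range somewhat above the reference
  maxima. The fixture accepts this documented discrepancy rather than
  inventing side reactions. `k3 = 0` by default because GF4 is absent
  from enzyme-treated juice.
* **Designs.** The enzymatic design crosses five doses (9000–45000 U/L)
  with times 0/1/2/3/4/6 h round-robin to 75 samples, with 2 % relative
  lot-to-lot jitter on the starting composition; time 0 is included so
  sucrose spans from its untreated level (~42 g/L) down to a few g/L.
  The FOS-addition design is the packaged 18-row reference table used
  verbatim; the commercial formulation compositions behind it are not
  public, so rows are used directly rather than reconstructed.

**What passing tests do and do not show.** The fixtures share the real
system's geometry — overlapping bands, additive mixing, realistic noise
floor, collinear oligomer concentrations — but not matrix effects of
acids and pigments, ATR penetration-depth physics, temperature drifts,
or instrument line-shape (the grid is treated as exact samples;
apodization smoothing is not emulated). Accuracy on these fixtures
demonstrates that the algorithms are implemented correctly and behave as
expected in the intended regime; it is not a validation against real
juice spectra, which are not publicly deposited.

## Numerical details and degenerate inputs

* Grids are stored ascending with both endpoints inclusive (so
  1250–900 cm⁻¹ at 2 cm⁻¹ has 176 points); descending display is a
  rendering concern. Non-divisible spans are rejected with the remainder
  named; duplicated or non-uniform axes are rejected at I/O time with
  the offending row indicated.
* The linear solve verifies its own residual (≤ 10⁻⁸ relative) after
  passing the condition cap.
* Fold assignment, lattice jitter and noise all draw from isolated RNG
  scopes that restore the caller's `.Random.seed`, so seeded package
  calls never perturb a user's random stream.
* Degenerate cases with defined behaviour: a flat spectrum yields an
  empty peak set (not an error); `n = K` subset search returns its only
  subset regardless of error; a zero-variance response, an empty
  selection, an all-singular candidate set and a region overlapping the
  derivative margin are all hard errors with specific messages.

## Problem sizes used by the tests

The default test suite and the acceptance script run entirely on
synthetic data at the study's native sizes — 75-sample enzymatic fixture,
18-sample FOS design, 1801-point grids, all 8568 five-wavenumber
subsets — which complete in seconds; smaller fixtures (10–40 samples) are
used inside unit tests where the full size adds nothing to the property
being checked.

## Known limitations

* The exact wavenumber sets reported for real spectra (e.g. winning SE
  subsets) depend on the measured standards and are not reproducible
  from synthetic profiles; the package asserts structure (counts,
  exactness, nesting, orderings), not those literal sets.
* Pattern C is asserted to be no worse than pattern B per sugar with a
  0.05 g/L allowance: where B already sits at the fixture's noise floor,
  fold-assignment noise can leave C statistically tied rather than
  strictly better.
* The SE method supports only square systems by default; the
  over-determined least-squares variant exists behind a flag and is not
  part of the validated workflow.
* JCAMP-DX support is a minimal read-only subset (`##XUNITS=1/CM`,
  AFFN `(X++(Y..Y))` tables); vendor binary formats and resampling
  between mismatched grids are out of scope by design — datasets must
  share a grid.
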