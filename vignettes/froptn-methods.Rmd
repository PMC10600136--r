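---
title: "Transition-network analysis of hemoglobin time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transition-network analysis of hemoglobin time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(froptn)
```

# The model

Resting-state near-infrared measurements of tissue yield, per voxel, two
independent time series: deviations of oxy- and deoxyhemoglobin
concentration about their temporal means (ΔoxyHb, ΔdeoxyHb, molar).  Three
dependent components follow algebraically: ΔtotalHb = ΔdeoxyHb + ΔoxyHb,
ΔHbO₂Exc = ΔdeoxyHb − ΔoxyHb (oxygen exchange), and the saturation
deviation ΔHbO₂Sat = 100·Δ(oxyHb/totalHb) in percent.  `froptn` analyzes
the joint dynamics of these five components with a *fixed-reference
ordinal partition*: each sample is labelled by the algebraic signs of the
five components relative to their temporal means, a fixed reference, in
contrast to ordinal-pattern networks built on moving windows.

Because the three derived components are linear (to first order) in
(ΔtotalHb, ΔHbO₂Sat), the five zero-crossing loci are lines through the
origin of that plane.  Five distinct lines cut the plane into exactly ten
sectors, so only ten of the 2⁵ = 32 sign permutations can occur.  Each
sector is a *state*; crossing one null line flips exactly one component's
sign, so the cyclic distance between two sectors equals the number of
components that change sign during the transition between them — this is
the transition *class* m ∈ {0, …, 5}.

Consecutive frames define a synchronous transition
`k = 10 (s1 − 1) + s2`, including self-transitions, giving 100 transition
types — the edges of a fully connected 10-node Markov graph.  Eighteen
per-type coefficient classes serve as edge weights: the transition
probability (percent), pre- and post-transition dwell times (seconds),
and, for each component, pre- and post-transition means and the flux (mean
per-occurrence change).

# Parameters that matter

* `s0` — baseline saturation fraction oxyHb/totalHb (dimensionless,
  default 0.7).  It orients the derived-component null lines: the deoxy
  null has slope 100(1 − s0)/total0 (> 0), the oxy null −100·s0/total0,
  the exc null 100(1 − 2 s0)/(2·total0).  Only Δ-series are observable in
  image space, so absolute baselines must be supplied; 70% saturation at
  `total0` = 1e−4 M total hemoglobin is a typical soft-tissue operating
  point.  These defaults are a documented convention, configurable in
  every entry point, not an empirical fit.
* `frame_rate` — 1.8 frames/s by default, matching the acquisition rate
  the method was designed around; it only converts dwell times from
  frames to seconds.
* averaging `scheme` — `"GA"` (grand average over all occurrences,
  the default and the authoritative definition), `"TMSM"` (spatial mean
  per time step, then temporal mean over steps with occurrences) and
  `"SMTM"` (temporal mean per voxel, then spatial mean).  The alternative
  schemes are the natural readings of their names; GA is used everywhere
  unless explicitly requested.

# Geometry conventions and numerical choices

* **State numbering.** State 1 is the sector swept first counterclockwise
  from the positive ΔtotalHb axis; numbering proceeds counterclockwise,
  so antipodal sectors differ by 5.  Every derived quantity (classes,
  reversal categories, coefficient values) is invariant under cyclic
  relabelling; `state_geometry(relabel =)` rotates labels if another
  published convention must be matched.
* **No all-positive state for s0 > 0.5.**  When total and saturation
  deviations are both positive, oxyHb rises faster than deoxyHb, so the
  exchange component ΔHbO₂Exc = ΔdeoxyHb − ΔoxyHb is necessarily
  negative.  The sector containing the first quadrant therefore carries
  the sign vector (+, −, +, +, +), not (+, +, +, +, +); a sign pattern of
  all-plus never occurs in the canonical regime.
* **Zeros and boundary points.**  Exact zeros take the positive sign.
  When several components are simultaneously zero (the origin, crossings
  of null lines) the sign pattern can be illegal; such samples are
  resolved by an angle lookup in the (ΔtotalHb, ΔHbO₂Sat) plane, a
  deterministic tie-break.  Observed sign vectors that are illegal with
  *nonzero* components arise only when inputs violate the component
  dependencies (e.g. through the nonlinearity of the saturation
  computation far from baseline); these fall back to the nearest sector by
  angle, the count is reported, and a fallback rate above 1% is an error.
* **Scaled assignment plane.**  Null-line angles are computed in scaled
  coordinates u = 100·ΔtotalHb/total0, v = ΔHbO₂Sat, where slopes become
  order-one numbers ((1 − s0), −s0, (1 − 2 s0)/2); in raw molar/percent
  units the lines are numerically near-vertical.
* **Dwell-time rules.**  Pre-dwell of a first-step occurrence and
  post-dwell of a last-step occurrence are undefined and excluded from the
  sums, which are nevertheless normalized by the full occurrence count, as
  the defining equations state.  Within a run of equal states, consecutive
  self-transition occurrences would yield nested dwell values; only the
  largest pre- and post-dwell per consecutive sequence contributes (the
  run-max rule).  A consequence worth knowing: for a long uniform-chain
  run, self-type dwell times converge to exactly one frame.  The run-max
  rule is applied to self-transition types only, as stated; whether it
  should also trim runs feeding non-self transitions is left as a
  sensitivity question.
* **Missing coefficients.**  A transition type with zero occurrences has
  probability 0 but *missing* (NA) dwell/mean/flux values — never zeros —
  so co-dependence fits are not biased by phantom points.
* **Conic fitting.**  `conic_fit()` minimizes the algebraic residual
  under Taubin's gradient normalization, solved as a generalized
  eigenproblem (Schur complement to eliminate the constant term, Cholesky
  whitening, symmetric eigendecomposition).  Data are centred and scaled
  internally; the conic *type* is classified in the standardized frame,
  where the discriminant test B² − 4AC ≷ 0 is scale-free (conic type is
  affine-invariant), while center, vertices and foci are reported in the
  fit frame (optionally with the abscissa pre-multiplied, e.g. by 1e6,
  when the two axes are many orders of magnitude apart).  Coefficients
  are additionally reported in original units with unit norm.  Collinear
  point sets return a flagged degenerate fit (the squared best line), not
  an error.  The published description of the fit algorithm admits
  variants; the Taubin variant was chosen and is validated by synthetic
  conic recovery (vertex error well under 5% at 1% noise).
* **Regression comparison.** Slopes/intercepts of two independent
  double-reciprocal fits are compared with t statistics built from the
  coefficient standard errors, df = n1 + n2 − 4 (equivalent to
  interaction terms in a pooled model); the source analysis does not name
  its test, so this standard choice is documented here.
* **Welch and paired tests.**  Category comparisons (sign-reversal
  tables, marker groups) use unequal-variance t tests; between-group
  comparisons of the same transition types use correlated-samples
  (paired) t tests.  Raw p-values are reported; a Benjamini–Hochberg
  column is emitted for transparency but plays no role in any decision.
* **t′ scores and amplitudes.**  Per-breast coefficient vectors are
  standardized against the contralateral breast's mean and SD across all
  100 types, and the flux-vector amplitude is the Euclidean norm of the
  (ΔtotalHb flux, ΔHbO₂Sat flux, Δ(dwell time)) t′ triple.  Rank-order
  categories follow the four published orderings of the |t′| magnitudes;
  the two orderings with the dwell component largest go to an `"other"`
  bucket, and ties are broken by the fixed precedence total > sat >
  dwell.  Log transforms in double-reciprocal fits are applied after
  group-mean averaging of the reciprocals, matching the plotted axes; the
  alternative order is noted as an open question.

# What the synthetic generator emulates — and what it does not

`generate_hb_series()` produces a paired ("affected"/"unaffected")
series: a shared slow oscillation in the 0.08–0.12 Hz vasomotor band
(frequencies are not specified by the source beyond "vascular
pulsatility"; the band is a configurable choice), with the total-Hb and
saturation projections in quadrature so trajectories loop through all ten
sectors, plus voxel-specific AR(1) noise with a ~5 s correlation time.
Amplitudes default to 4e−8 M (total) and 0.04% (saturation) — the
magnitude range of reconstructed breast images — and the affected
member's saturation spread is multiplied by `sat_inflation` (default 2),
mimicking the exaggerated saturation span of tumor-bearing tissue.  At
the default size (700 frames × 2000 voxels) every one of the 100
transition types occurs.

The generator emulates amplitude scales, autocorrelation, oscillation and
an inter-breast asymmetry.  It does *not* emulate spatial correlation
between voxels beyond the shared oscillation, reconstruction artifacts,
physiological nonstationarity, or any disease biology; a green test
establishes computational correctness of the pipeline on data with the
right statistical shape, not clinical validity.

`markov_amplitude_fixture()` is the parameter-recovery harness: states
are drawn from an explicit Markov chain, and either (a) component values
are state representatives plus noise (validated for sign consistency
against the sector table), or (b) total/saturation series are cumulative
walks whose per-occurrence increments inject a known
probability–flux coupling |φ|(P) = Vmax·P/(Km + P), applied
antisymmetrically (positive for s1 < s2) so that fluxes of reciprocal
transition types cancel, as they must for any series of bounded drift.
The full pipeline (suite → double-reciprocal fit on classes 3–5) recovers
Vmax and Km within a few percent at the default fixture size.

`geometric_null_model()` reproduces the geometric null: points uniform
over a plane rectangle, transitions down-weighted by a monotone
decreasing function of distance.  Under a flat kernel the per-type
pre-transition means collapse to sector centroids; under a distance
kernel the same-pre-state "spokes" bend (principal-axis linearity clearly
below 1), the null model's qualitative signature.

`surrogate_series()` provides time shuffling (destroys dynamics,
preserves marginals exactly) and per-voxel phase randomization (preserves
each channel's periodogram exactly and the oxy/deoxy cross-spectrum by
reusing the random phases within a voxel).  The exact surrogate
constructions used in the source's noise studies are not described in its
main text; these two standard surrogates are documented stand-ins.  On
oscillatory synthetic data the (post-transition mean, flux) co-dependence
of total hemoglobin is stably hyperbolic; after time shuffling the
classification collapses toward the degenerate boundary and is no longer
a stable hyperbola — structured co-dependence is not an artifact of the
coefficient algebra alone.

# Worked example

```{r example, eval = FALSE}
sim <- generate_hb_series(sim_config(n_frames = 400, n_voxels = 200, seed = 1))
geom <- state_geometry(s0 = 0.7, total0 = 1e-4)
suite_T <- adjacency_suite(sim$affected, geom)    # tumor-like breast
suite_U <- adjacency_suite(sim$unaffected, geom)

# t-prime normalization against the contralateral breast, Eq.-style
tp <- function(coef) tprime_scores(suite_coefficient(suite_T, coef),
                                   suite_coefficient(suite_U, coef))
A <- vector_amplitude(tp("flux_total"), tp("flux_sat"), tp("dwell_flux"))
cls <- decode_transition(1:100)$class_m
lineweaver_burk(suite_coefficient(suite_T, "prob"), A, subset = cls >= 3)
```

# Known limitations

* The published correspondence between circled state labels and sectors
  is not recoverable from text alone; the counterclockwise convention
  here is self-consistent and relabelling is supported, but absolute
  state numbers may differ from the published figure.
* TMSM/SMTM follow the natural reading of their names; the precise
  supplementary definitions were not available.
* Absolute saturation baselines are a convention (defaults s0 = 0.7,
  total0 = 1e−4 M), not a measured value; saturation values scale
  accordingly, though states and classes are insensitive to moderate
  baseline changes.
* Headline empirical values of the motivating study (group-mean tables,
  specific correlation extrema, specific regression r values) depend on
  its clinical dataset and are not reproduced at desk scale; the package
  reproduces the method's combinatorial structure exactly and its
  estimators' behavior on synthetic data with known ground truth.
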