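---
title: "Analysing wide-line NMR melting diagrams with hydromelt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing wide-line NMR melting diagrams with hydromelt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydromelt)
```

## The measurement and the model

When a frozen protein solution is thawed slowly through equilibrium states,
water molecules bound at the protein surface start to rotate — "melt" — one
potential-barrier class at a time. Wide-line ^1^H NMR detects this as
motional narrowing, and the fraction of mobile water protons `n` plotted
against temperature is the *melting diagram* (MD). Temperature is used on
the normalized fundamental scale

$$T_{fn} = T / 273.15,$$

which maps the melting point of ice to 1, and is read as a potential-barrier
scale through the molar heat of fusion of ice,
$E_a = 6.01\ \mathrm{kJ\,mol^{-1}} \times T_{fn}$. A globular protein melts
its hydration shell in a narrow barrier band (a wide plateau in the MD); an
intrinsically disordered protein (IDP) keeps recruiting mobile water as the
temperature rises.

`hydromelt` models the MD as a segmented curve:

* `n = 0` below the onset `T_fn0`;
* a plateau `n = A` on `[T_fn0, T_fn1)`;
* a linear regime `n = A + B (T_fn - T_fn1)` on `[T_fn1, T_fn2)`;
* an added quadratic term `C (T_fn - T_fn2)^2` beyond `T_fn2`.

The quadratic term is *added to the continuing linear term*. This is the
only continuity structure under which a single parameter set jointly
reproduces the curve value at `T_fn2` and at `T_fn = 1` for the reference
parameter sets shipped in the tests; a cubic term is deliberately not
included (it adds nothing on data of this extent and noise level).

The *extended* variant describes melting diagrams with three further
features seen in some mutants: a gradual onset (modelled as a linear ramp
from `T_fn_onset` to `T_fn0` — the fewest-parameter choice; the true shape
below the effective onset is not identified by the data), a jump of size
`delta` in `n` at the plateau end, and a slope change at `T_fnx` from `B1`
to `B2` (value-continuous). The jump size is typically not measurable
directly; when a curve value at `T_fn2` is known, `delta` is fixed by
continuity.

## Scales and hydration conversions

All conversions live in one place and are pure:

```{r}
ea_from_tfn(0.824)       # potential barrier at a plateau onset, kJ/mol
celsius_from_tfn(0.879)  # same breakpoint in degrees C
```

The mobile fraction `n` converts to hydration measures through the sample's
water:protein mass ratio `r = 1000 / c` (concentration `c` in mg/mL; the
protein's own volume is neglected, a < 4% correction at 50 mg/mL, below the
experimental uncertainties):

* `h = n r` — g mobile water per g protein,
* `W = (n/2) r M_r / 18.015` — mobile waters per protein molecule
  (the 1/2 counts two protons per water molecule),
* `naa = W / a` — mobile waters per residue.

Note that `W` and `naa` carry the mass ratio `r`: the mobile *fraction* is
measured relative to all water protons in the sample, so the count of
mobile waters per protein scales with how much water surrounds each protein
molecule. About `h = 0.3` corresponds to a complete first hydration layer;
`h = 0.2` is roughly the functional minimum.

```{r}
wt <- read_fasta(system.file("extdata", "alpha_synuclein_wt.fasta",
                             package = "hydromelt"))
s <- sample_info(apply_mutation(wt, "A30P"), concentration = 50)
hydration_from_n(0.0156, s, tfn = 0.824)
```

Molar masses use average (not monoisotopic) residue masses, because the
hydration ratios are bulk mass quantities.

## Fitting: profiled least squares with exact amplitude solves

For fixed breakpoints the model is linear in the amplitudes, so `md_fit()`
profiles them out exactly:

1. **Grid stage.** All admissible ordered breakpoint triples on a coarse
   grid (step 0.005) are scored; for each `(T_fn0, T_fn1)` the 3×3 normal
   equations are solved simultaneously for every `T_fn2` candidate, so the
   stage is fast. Each segment must contain at least `min_seg = 2`
   observations. Ties are resolved toward the smaller `T_fn1` by scan
   order.
2. **Kink refinement.** `T_fn1` and `T_fn2` move the position of slope
   kinks, so the residual sum of squares is piecewise smooth in them;
   they are polished with `nlminb` from the five best grid candidates.
3. **Onset scan.** `T_fn0` is different: it enters the objective only
   through which observations are compared against the zero baseline, so
   the RSS is a *step function* of `T_fn0` and gradients are useless.
   The fitter scans all partition classes exactly and reports the onset as
   the midpoint of the gap between the last excluded and first included
   observation — inside that gap the onset is simply not identifiable from
   the data, and the midpoint bounds the error by half the local grid
   spacing.
4. **Exact polish.** Conditional on the segment assignment, the plateau
   level, the line and the continuing quadratic can be solved in closed
   form and the interior breakpoints recovered from continuity. On
   noise-free input this recovers the generating parameters to machine
   precision (residual sums of squares around 1e-29); on noisy input it is
   one more candidate and the best RSS wins.

Observations below the candidate onset are *not dropped*: they are
compared against a zero prediction. Dropping them (an alternative sometimes
suggested when sub-onset points may be unobserved rather than zero) makes
the onset unidentifiable, because excluding more points can only lower the
RSS. Users with genuinely unobserved low-temperature points should simply
not include those rows in the input.

Amplitude non-negativity is enforced by clamp-and-refit: if the
unconstrained solve returns a negative amplitude, the offending column is
clamped at zero, the rest refitted, and a warning raised. Uncertainties for
the amplitudes come from the final linear solve
(`sigma^2 (X'X)^{-1}` with `sigma^2 = RSS/(nobs - npar)`); breakpoint
uncertainties are reported as `NA` rather than pretending the linearization
holds across a kink.

Fitting involves no randomness: identical input gives identical output.

The brute-force `md_fit_grid()` (default step 0.001) exists as an
independent check: the full fitter must never return a larger RSS than the
grid search on the same data, and the test suite asserts this on seeded
noisy series.

The extended variant is fitted by initializing from a standard fit,
scanning onset/slope-change candidates coarsely, then refining all five
breakpoints by deterministic coordinate scans plus a joint `nlminb` polish.
With a jump in the model, the plateau-end breakpoint is only identifiable
up to the gap between the adjacent observations (any `T_fn1` within the gap
reproduces the data exactly, with `delta` unchanged); tests therefore
compare the fitted *curve*, and the breakpoints only to grid resolution.

## Derived quantities

`md_differential()` returns the analytic derivative of the fitted curve
(the differential melting diagram): zero on the plateau, the slope on
linear regimes, linear growth beyond `T_fn2`. The extended-variant jump is
rendered as a single-bin rectangular spike of height `delta/step`, so its
trapezoid integral equals `delta`. The evaluation grid is augmented with
points at and just below each discontinuity, which makes the trapezoid rule
exact segment by segment; the integral over `[T_fn0, 1]` then equals
`n(1) - A` to better than 1e-6, a conservation law the tests verify.

`het_report()` computes the heterogeneity statistics of the water-binding
barrier distribution:

```{r}
a30p <- md_params(A = 0.0156, B = 0.24, C = 50,
                  T_fn0 = 0.824, T_fn1 = 0.879, T_fn2 = 0.959)
het_report(a30p, sample = s)
```

`HeR = (1 - T_fn1)/(1 - T_fn0)` measures how much of the barrier range up
to the melting point of ice is covered heterogeneously; `100 (1 - HeR)` is
the percentage with homogeneous barrier distribution (rounded to integer
for reporting). `HeR_n = n_he/(n_ho + n_he)` is the heterogeneously bound
fraction of the mobile water, with `n_ho = A` and
`n_he = n(T_fn = 1) - A`. `HeM = (B + 2C)/(1 - T_fn1)` measures the rate of
heterogeneity near 0 °C. For the extended variant, `n_ho` is the plateau
amplitude `A` (not the ramp content), the slope used in `HeM` is `B2` (the
one active approaching `T_fn = 1`) and `T_fn0` is the effective plateau
onset; the report records both choices.

`md_classify()` separates IDP-like from globular-like diagrams: a curve is
globular-like when the plateau spans at least half of the barrier range
above the onset *and* the post-plateau rise contributes less than half of
`n(1)`. Both thresholds are arguments; the defaults encode the qualitative
contrast between the two protein classes and are not sharp boundaries.

## Secondary-structure consensus

Predictor tracks are aggregated by per-residue plurality vote after mapping
eight-state tracks to three states (G, H, I → H; E, B → E; T, S, L → C).
Two policies are deliberate:

* **Vote ties go to coil**, the "remaining" class — claiming a structured
  state on a split vote would overstate the evidence.
* **The minimum-run filter runs after voting** (structured elements need at
  least `k = 4` consecutive residues; shorter H/E runs become C). Filtering
  each track first and then voting would let the vote re-create sub-minimum
  elements, defeating the filter. The filter is idempotent and never
  increases structured content.

Disorder/binding score tracks are thresholded strictly: a score of exactly
0.5 does *not* call a region ("above 0.5").

## The synthetic-data generators

Every input the pipeline consumes can be generated with known ground truth:

* `gen_md()` — model curve plus homoscedastic Gaussian noise on `n`,
  clipped at zero. Default `sigma = 5e-4`, about 3% of a typical plateau
  amplitude. Real diagrams may have temperature-dependent noise and
  hysteresis between cooling and heating sweeps; neither is simulated, so
  passing recovery tests show correctness of the estimator under the
  stated noise model, not robustness to instrumental drift.
* `gen_ss_ensemble()` — corrupts a true label string independently per
  residue (probability `err`, replacement uniform over the *other*
  symbols). Real predictors make correlated errors (they share training
  data and profiles), so real consensus accuracy is worse than this model
  suggests; tests calibrated on it say nothing about systematic predictor
  bias.
* `gen_score_track()` — piecewise-constant segment means plus clipped
  Gaussian noise.

All generators are seeded and restore the caller's RNG state.

## Problem sizes and numerical conventions

The test suite and examples use 40–60 point diagrams on `T_fn` in
`[0.76, 1.00]`, 100 replicates for recovery statistics, and 10 seeded
datasets for the optimizer-vs-grid comparison — sizes representative of
real melting diagrams, where each point is a separately equilibrated
temperature. Key tolerances: noise-free refit RSS below 1e-18 (observed
around 1e-29), trapezoid conservation 1e-6 on a 1e-4-spaced grid, median
breakpoint recovery error under 0.01 at `sigma = 5e-4`.

Known limitations: the pipeline starts from `(T_fn, n)` series — raw
lineshape decomposition is out of scope; breakpoint uncertainties are not
quoted; the extended-variant fit assumes the data cover the onset ramp; and
composition percentages from real predictor ensembles depend on the
predictors supplied, which the package consumes but does not run.
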