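---
title: "Methods: designs, surfaces, desirability, Bayesian optimization and PK metrics in qbdoe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designs, surfaces, desirability, Bayesian optimization and PK metrics in qbdoe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qbdoe)
```

qbdoe implements the computational side of a quality-by-design formulation
campaign: screen factors with a Plackett–Burman design, model the critical
quality attributes on a central composite design with a full quadratic
response surface, pick an operating point by desirability, and—as a
sequential alternative—optimize a single response with Gaussian-process
Bayesian optimization. A synthetic experiment oracle closes the loop so
that every algorithm is testable without a laboratory. This vignette
records the models, the defaults and why, and the judgement calls.

## Experimental designs

**Plackett–Burman.** `generate_plackett_burman()` builds the canonical
12-run design by cycling the generator row (+ + − + + + − − − + −) and
appending the all-minus run. Any cyclic construction gives the defining
properties the tests assert: every column balanced (six +1, six −1) and
all column pairs orthogonal. Columns not assigned to real factors are kept
as *dummy* columns: their apparent "effects" are pure noise contrasts, and
`screen_effects()` uses their root-mean-square as the standard error of a
real effect. Because orthogonal contrasts of i.i.d. normal errors are
i.i.d., the resulting statistic is exactly t-distributed with one degree
of freedom per dummy column; a simulation test confirms the nominal 5%
type-I rate. With zero dummy columns effects are returned untested, with a
warning—there is no error estimate to be had.

**Central composite.** `generate_ccd()` produces the 3-factor, 5-level,
2-block CCD: the 2³ cube plus `n_center_cube` centre replicates form
block 1; the six axial points at coded ±α plus `n_center_axial` centre
replicates form block 2. The case-study defaults are α = 1.633 and 4 + 2
centres (20 runs). α is taken as given rather than recomputed from
orthogonal-blocking formulas (for this centre allocation the
orthogonal-blocking value is ≈1.633 anyway). Run codes CC01…CC20 are
assigned deterministically; randomizing the run order is available behind
a seed but off by default so that designs are stable fixtures. Coded and
actual scales are linked by `actual = center + coded * half_range` per
factor; both are carried in the design object.

A note on the packaged 20-run fixture (`table4_ccd`): the printed record
does not label blocks or point types, so those columns were derived from
the coded levels, and the centre replicates were allocated to blocks by
the printed run-order grouping (runs 1–10 with the axial points, runs
11–20 with the cube). That is the reverse of the stated 4-in-cube /
2-in-axial allocation, which `generate_ccd()` follows; the fixture records
history, the generator follows the design description. The only quantity
that depends on the fixture's block labels is the pooled centre-point
noise preset `center_point_sd()`.

## The quadratic response surface and its ANOVA

`fit_quadratic()` estimates the 10-coefficient full quadratic by ordinary
least squares, optionally absorbing the design blocks as centred fixed
effects (the default for blocked CCDs). Block offsets are diagnostics
only; `predict()` is the pure polynomial. No term selection is performed:
the case study reports all ten coefficients, and dropping terms would
change the meaning of the packaged coefficient sets.

`rsm_anova()` decomposes the corrected total sum of squares sequentially
into block, model (the nine surface terms jointly, after block) and
residual, so those three rows always add up exactly. Per-term rows carry
partial (Type-III) sums of squares—each term against the full model—which
matches the convention of the commercial DoE software this workflow
usually runs in; partial rows do not (and need not) sum to the model row.
The residual splits into pure error, pooled over replicate groups
(identical factor settings within a block), and lack of fit. R² is
`1 − SS(Residual)/SS(Corrected Total)`, i.e. block variation stays in the
denominator; this reproduces the case study's printed arithmetic
(1 − 350.9/11920.4 = 0.9706).

**A data honesty note.** Refitting the verbatim 20-run fixture does *not*
reproduce the study's printed ANOVA (R² comes out ≈0.50, not 0.97): the
printed centre-point responses for Y1 (90, 26, 30, 37.8, 26.3, 30) are
mutually inconsistent with the printed pure-error sum of squares, and one
of them (90) is a suspected typographical error. The fixtures are shipped
byte-for-byte as printed—historical records, not cleaned data—and the
published coefficient sets are exposed separately via
`reference_surface()`. All printed-value tests anchor on the internally
consistent quantities (the Y1 ANOVA identities, the predicted values, the
level map), never on a refit of the inconsistent table.

## Desirability

Each response to be maximized gets a one-sided Derringer–Suich ramp:
d = 0 at or below the lower bound, 1 at or above the target,
`((y − L)/(T − L))^weight` between. Defaults follow the case study's
stated CQA floors (L = 70 mg/cm² for Y1, 40 for Y2); the study does not
publish its targets or weights, so its printed desirability values
(0.92/0.99/0.90) are qualitative context only and are not asserted
anywhere. The composite is the geometric mean, so any zero component
vetoes a candidate. `optimize_desirability()` scans a regular grid
(51 points per axis by default, deterministic, ties broken by grid order)
and polishes the best cell with box-clipped Nelder–Mead, accepting the
refined point only if it does not lose to the grid—so refinement is
provably monotone.

## Gaussian-process Bayesian optimization

The surrogate is a GP with constant mean and ARD Matérn 3/2 kernel
k(x,x′) = σ²(1 + √3·r)·exp(−√3·r), r the lengthscale-scaled distance,
on inputs rescaled to the unit cube by the search bounds and outputs
standardized. The nugget defaults to 1e-6 (near-noiseless interpolation of
deterministic oracles; an estimated nugget is available for noisy ones).
Hyperparameters maximize the log marginal likelihood with L-BFGS-B from
10 seeded starts, lengthscales bounded in [1e-3, 1e3].

**Why MAP, not pure ML.** On noise-free smooth responses the marginal
likelihood is nearly flat in the lengthscales: on a representative stalled
run the difference between a unit-cube lengthscale of 0.8 and of 110 was
about two nats. Pure ML then happily selects near-infinite lengthscales,
which collapse the posterior standard deviation everywhere and starve the
acquisition functions of the uncertainty they exist to exploit—observed as
runs that re-propose the same corner until the budget is gone. `fit_gp()`
therefore adds a weak lognormal prior on the lengthscales (median 0.5,
sdlog 1.5; `ls_prior = NULL` restores pure ML). The penalty is negligible
wherever the data are informative and only resolves the flat direction;
mainstream BO toolkits regularize the same way. With it, 20/20 seeded
closed-loop replicates reach the true surface optimum within 2 response
units, with a median of 15 total experiments (8 initial + 7), versus the
20 runs the one-shot CCD requires.

Acquisitions follow the maximization convention: Expected Improvement
EI = (μ − y*)Φ(z) + σφ(z), z = (μ − y*)/σ, degenerating to
max(μ − y*, 0) at σ = 0; and the upper Confidence Bound μ + κσ with
κ = 2 by default ("Confidence Bound" is interpreted as the upper bound
since the objective is maximized). `propose_batch()` returns one argmax
per acquisition, found by a seeded random multistart (50 candidates plus
the training locations), L-BFGS-B refinement of the best few, and three
rounds of focus search—resampling in a box that halves around the running
best—because sharply peaked EI surfaces are easy to miss with uniform
candidates alone. Both proposals in an iteration come from the *same*
posterior (no fantasizing): in the emulated lab workflow both experiments
are run before the model is updated. Duplicate acquisitions therefore
yield duplicate proposals, which is documented behaviour, and a flat
acquisition falls back to the centre of the bounds with a warning.

`run_bo()` runs a fixed number of iterations (default 6, mirroring the
case study's 8 + 6×2 = 20-experiment budget); an improvement-based early
stop (< 0.5 response units of incumbent gain over the last two complete
iterations) is available via `early_stop = TRUE`. The exact coordinates
the original campaign proposed (its BO01–BO12) depend on unpublished
seeds and optimizer internals and are not reproduced; they ship as
fixtures for context, and the package's claim is the behavioural one
tested in acceptance: the closed loop finds the optimum reliably within
the same budget.

## The synthetic oracle: what it emulates and what it does not

`oracle_config()` wraps the published quadratic surfaces (or any custom
one) with optional Gaussian replicate noise. Noise draws are
counter-based—derived deterministically from (seed, replicate id, x)—so
replicates are reproducible in any evaluation order. The default
`noise_sd = 0` is a deliberate stated world: algorithm correctness is
tested against an exactly known truth. A "realistic" preset,
`center_point_sd()`, pools the centre-replicate scatter of the packaged
CCD at load time (≈10 response units for Y2) rather than hard-coding a
number. The oracle emulates *response values only*: it knows nothing of
milling physics, particle-size dynamics or dissolution kinetics, and a
green closed-loop test establishes that the algorithms optimize the
stated surface—not that the surface is a good model of the laboratory.

`simulate_pk_profile()` provides the standard one-compartment oral model
C(t) = D·ka/(V/F·(ka−ke))·(e^(−ke·t) − e^(−ka·t)), with optional
lognormal multiplicative noise, to exercise the NCA code against closed
forms (AUC₀₋∞ = D/(V/F·ke), tmax = ln(ka/ke)/(ka−ke)). The flip-flop
degenerate case ka = ke is rejected at configuration time.

## In-vitro / in-vivo metrics

All bio-metrics are closed-form and unit-explicit. Viability is
100·(group − blank)/(control − blank). Papp is flux/(area·C₀), converted
to cm/s when the flux is per-minute (assay-native units are declared in
the constructor, never guessed). The dissolution correction adds back the
drug removed by sampling, `C'ₙ = Cₙ + (Vs/V)·ΣᵢCᵢ (i<n)`, and the
intrinsic dissolution rate is the OLS slope of corrected dissolved mass
per disc area versus time over a stated window (mg/min/cm²; the standard
Wood-apparatus disc is 0.5 cm²). Fold changes round half-up at the
printed precision, since printed pharmacology tables round half-up and
base R rounds half-even.

NCA uses the linear (linear-up/linear-down) trapezoid throughout—the
simplest defensible default; the terminal rate ke is minus the OLS slope
of log-concentration over the last 3 positive samples by default
(configurable), AUC₀₋∞ adds C_last/ke, t½ = ln2/ke, and MRT is
AUMC₀₋∞/AUC₀₋∞ with the standard t·C tail. A non-negative terminal slope
returns NA for the extrapolated quantities with a warning rather than a
nonsense number. Absorption-rate-constant estimation is out of scope:
those values in the packaged PK table came from compartmental software,
and the method of residuals is ambiguous for these profiles. Known NCA
limitation, asserted in tests: when ka approaches ke the terminal phase is
not mono-exponential within any finite horizon, and the log-linear tail
fit is biased by construction—recovery tests therefore use the
physiologic ka ≥ 2.5·ke regime (the case study's own fitted ratios are
roughly 10–30).

## Numerical choices and degenerate inputs

* Kernel Cholesky factorizations get escalating jitter (1e-10 up to 1e-2)
  only when needed; failure past that raises an error rather than
  returning garbage.
* Posterior variances are clipped at zero before the square root;
  at a training point with the default nugget the reported sd is
  O(√(2·nugget)), i.e. ~1e-3 standardized, and shrinks to below 1e-6 only
  as the nugget is reduced accordingly.
* Constant responses: the GP standardizer falls back to unit scale
  (avoiding 0/0), the quadratic fit returns a pure intercept, and the
  desirability optimizer reports an all-zero flag instead of failing.
* Ties: grid scans take the first maximum in lexicographic order;
  `which.max` semantics, documented and tested.
* Exact-fit ANOVA (zero residual) reports undefined F statistics as NA.
* Seeds: every stochastic routine takes an explicit seed and derives
  per-iteration streams from it; identical configuration + seed is
  bit-reproducible end to end.

## Known limitations

* The desirability values printed in the case study's validation table
  are not reproducible without the commercial software's internal
  normalization; only the qualitative conclusions are asserted.
* The GP engine targets small campaigns (tens of runs); dense Cholesky
  refits every iteration would not scale to thousands of points.
* No multi-objective BO, no fantasized batches, no input warping, no
  compartmental PK fitting, no bioequivalence statistics, no
  dissolution-similarity metrics (f1/f2).
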