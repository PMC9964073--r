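# qbdoe

Quality-by-design (QbD) computation for pharmaceutical formulation
development, built around a worked case study: optimizing a dry co-milled
celecoxib (CXB) nanocrystal composition whose factors are the
excipient-to-drug weight ratios X1 = PVP/CXB, X2 = SLS/CXB and
X3 = MAN/CXB, and whose critical quality attributes are the dissolved drug
amounts Y1 (pH 12, 30 min) and Y2 (pH 1.2 + 0.2% SLS, 120 min).

The package is for formulation scientists and method developers who want
the full computational loop of such a study as tested, scriptable code:

* **Experimental design** — 12-run Plackett–Burman screening designs
  (with dummy-column error estimation) and 3-factor, 5-level, 2-block
  central composite designs with axial distance α (here 1.633), plus the
  coded ↔ actual affine transforms.
* **Response-surface modelling** — the 10-coefficient full quadratic
  y = β₀ + Σβᵢxᵢ + Σβᵢⱼxᵢxⱼ + Σβᵢᵢxᵢ², with blocked ANOVA
  (partial SS, lack-of-fit vs pure error, R²) and PB main-effect
  screening.
* **Desirability optimization** — one-sided Derringer–Suich ramps,
  geometric-mean composite, deterministic grid scan + Nelder–Mead polish.
* **Bayesian optimization** — an ARD Matérn 3/2 Gaussian-process
  surrogate (unit-cube inputs, standardized outputs, MAP-regularized
  marginal-likelihood fitting) with Expected Improvement
  EI(x) = (μ−y*)Φ(z) + σφ(z) and upper Confidence Bound μ + κσ
  acquisitions, two proposals per iteration from the same posterior.
* **Synthetic experiment oracle** — the case study's published quadratic
  surfaces as ground truth, Gaussian replicate noise with counter-based
  reproducible streams, one-compartment oral PK simulation, and verbatim
  fixtures of the study's printed data tables.
* **In-vitro / in-vivo metrics** — MTT viability %, apparent permeability
  Papp = (dQ/dt)/(A·C₀), withdrawal-corrected intrinsic dissolution rate,
  rounded fold changes, and non-compartmental PK (Cmax, tmax, AUC₀₋ₜ,
  AUC₀₋∞, ke, t½, MRT) with relative bioavailability
  100·(AUC_test/dose)/(AUC_ref/dose).

## Worked example

Fit the published 20-run CCD data and locate the desirability optimum:

```r
library(qbdoe)

design <- generate_ccd(celecoxib_factors(), alpha = 1.633)
t4     <- load_fixture("table4_ccd")          # 20 runs, Y1 + Y2, verbatim

fit <- fit_quadratic(design, t4[, c("code", "Y1")], "Y1")
anova_y1 <- rsm_anova(design, t4[, c("code", "Y1")], "Y1")
round(attr(anova_y1, "r_squared"), 4)
#> [1] 0.5045
```

That R² of 0.50 (instead of the study's reported 0.9706) is expected and
deliberate: the printed response table is internally inconsistent with the
printed ANOVA (one centre-point response of 90 against replicates of
26–37.8 is a suspected typographical error), and the fixtures are shipped
verbatim rather than "corrected". The published coefficient sets are
therefore exposed directly as ground-truth surfaces:

```r
m1 <- reference_surface("Y1")
predict(m1, c(1.5, 0.2, 0.5))
#> [1] 83.09648            # the study's printed prediction: 83.1

mods <- list(Y1 = m1, Y2 = reference_surface("Y2"))
specs <- list(Y1 = desirability_spec(70, 90),   # CQA floor 70 mg/cm2
              Y2 = desirability_spec(40, 50))   # CQA floor 40 mg/cm2
opt <- optimize_desirability(mods, specs,
         bounds_box(X1 = c(0.5, 1.5), X2 = c(0, 0.2), X3 = c(0.5, 1.5)))
opt
#> <desirability_result>
#>   best point:  X1 = 1.5, X2 = 0.2, X3 = 1.387
#>   composite desirability: 0.9583
```

The optimizer pushes PVP/CXB to its upper bound and SLS/CXB to 0.2,
matching the study's design-space conclusion; predicted responses at the
optimum are Y1 ≈ 88.4 and Y2 ≈ 50.0 mg/cm².

Close the loop in silico with Bayesian optimization of Y2 (8 published
starting runs, 6 iterations × {EI, CB}):

```r
cfg  <- oracle_config("Y2", noise_sd = 0)     # noise-free ground truth
tab2 <- load_fixture("table2_init")
trace <- run_bo(oracle_fn(cfg), as.matrix(tab2[, 1:3]), tab2$Y2,
                bounds_box(X1 = c(0.5, 2), X2 = c(0, 0.2), X3 = c(0.5, 2)),
                n_iterations = 6, seed = 1)
trace$incumbent_best
#> [1] 66.99043          # true constrained maximum: 67.0 at (2.0, 0.2, 0.96)
```

## Layout

R code per module: `R/design.R`, `R/rsm.R`, `R/desirability.R`, `R/gp.R`,
`R/bo.R`, `R/oracle.R`, `R/biometrics.R`, `R/io.R`. Fixtures:
`inst/extdata/*.csv`. Methods notes: `vignettes/qbd-methods.Rmd`.
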