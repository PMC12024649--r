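# gcsens — growth-coupled sensitivity of gene regulatory switches

Bacterial regulatory switches — positive feedback loops that flip a set of
genes on when an external signal crosses a threshold — do not have a fixed
threshold. Because a stable intracellular molecule is lost mainly by
dilution, its concentration decays at the growth rate λ, and every switch
built on such molecules becomes *less* sensitive the faster the cell grows.
`gcsens` is an R package for this growth-coupled sensitivity (GCS): it
implements the dynamical models that produce it, the phase-diagram and
threshold computations that quantify it, the optimality theory that links
it to concentration-dependent sugar preferences, and the bulk and
single-cell analysis pipelines that measure it, together with synthetic
data generators carrying full ground truth.

## The core quantities

Each switch circuit reduces to a scalar steady-state equation
`dx/dt = p(x, s, λ) − (λ+δ)·x` for its feedback protein (µM, hours), where
`s` is the external signal and δ a molecular decay rate. The package
locates all fixed points, classifies (doubling time × signal) space into
off / on / bistable, and extracts the saddle-node boundaries
`(s_low, s_high)` and their log-midpoint `s_center`.

For the *lac* operon the boundaries obey, exactly,

    c* = G · K_tau · (λ+δ)² / (α_imp · q_h(λ))

with `q_h` the full-induction production rate and `G` a pure number set by
the leak and the induction Hill coefficient. Three growth laws for the
full-induction expression level `y_h(λ) = q_h/(λ+δ)` cover the regimes of
interest: constant production (threshold ∝ (λ+δ)², the quadratic law),
the CRP "C-line" `y_h = y0·(1 − λ/λ*)` (threshold tracks the inverse Monod
function `K_s·λ/(λ_max − λ)` exactly when λ* = λ_max), and the translation
"R-line" `y_h ∝ λ` (threshold independent of growth rate).

On the estimation side the package provides the four-parameter Hill
induction-curve fit `α(c) = b(1 + f(c/k)^m)/(1 + (c/k)^m)`, a Bayesian
errors-in-variables log–log slope posterior with analytic marginalization
of the intercept and a scale-prior–optimized intrinsic scatter,
plate-reader growth-segment extraction with Miller-assay and fluorimetry
activity estimates, and single-cell lineage processing: per-cell growth
rates, photobleach correction `c = c_u(1 + β/λ)`, and quadrant-based
on/off switch detection on three-cell lineages.

## Worked example

```r
library(gcsens)

## critical TMG concentration of the lac switch vs doubling time
lac <- switch_preset("lac")
critical_curve(lac, c(1, 2, 4))
#>   doubling_time_h s_low s_high s_center
#> 1               1 20.01 158.49    56.31
#> 2               2  5.21  41.26    14.66
#> 3               4  1.41  11.16     3.96

## calibrate the CRP growth law so the bistable centre tracks inverse Monod
cal <- calibrate_cline(lac, sugar_monod_default("lactose"))
#> y0 = 46.4 uM, lam_star = 0.720 /h, tracking error = 3.2e-05

## concentration-dependent sugar choice: 40 uM glucose loses to saturating
## lactose, so only the lac switch is predicted supercritical
predict_induced_set(list(
  list(name = "glucose", concentration = 40,
       monod = sugar_monod_default("glucose")),
  list(name = "lactose", concentration = 550,
       monod = sugar_monod_default("lactose"))))
#>      name concentration_uM attainable_lambda supercritical   tie
#> 1 glucose               40         0.5982396         FALSE FALSE
#> 2 lactose              550         0.6214118          TRUE FALSE

## scaling exponent of the critical concentration (Bayesian slope posterior)
gd <- gen_threshold_dataset(lac, exp(seq(log(0.7), log(6), length.out = 8)),
                            sigma_rep = 0.15, n_rep = 3, seed = 42)
fit_loglog_slope(gd$points)
#> log-log slope: a = -2.000 +/- 0.054 (intrinsic scatter 0.109)
```

The critical curve falls ~4-fold per doubling-time doubling (the quadratic
law), the calibrated C-line pole `λ*` coincides with the lactose Monod
maximum and tracks its inverse Monod curve to a few parts in 10⁵, the sugar
choice flips exactly at the concentration where the two attainable growth
rates cross (~50 µM glucose against saturating lactose), and the fitted
exponent is the model's −2 with its posterior uncertainty.

Single-cell pipelines are exercised the same way: `gen_lineage_dataset()`
simulates mother-machine channels on glucose/lactose mixtures with
growth-rate fluctuations driving stochastic on/off switching, and
`channel_switches()` / `compare_switcher_growth()` recover the switch
events and the directional growth asymmetry (cells switching on grew
slower than their population beforehand; cells switching off grew faster).

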