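---
title: "Growth-coupled sensitivity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled sensitivity: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcsens)
```

# The science in one paragraph

For any intracellular molecule that is stable on the timescale of a cell
cycle, the decay of its *concentration* is dominated by dilution, so its
effective first-order loss rate is the growth rate itself. A regulatory
switch built on positive feedback therefore changes its sensitivity with
growth rate: the faster the cells grow, the more signal it takes to flip the
switch. `gcsens` implements this growth-coupled sensitivity (GCS) programme
end to end — four switch circuits as growth-rate-aware dynamical systems,
the phase diagrams and critical-concentration curves they generate, the
optimality theory connecting the lac operon's CRP growth law to
concentration-dependent sugar preferences, and the bulk and single-cell
estimation pipelines that measure these quantities from (synthetic) data.

# The switch models and their reductions

All four circuits reduce to one scalar equation
$\dot x = p(x, s, \lambda) - d(s, \lambda)\, x$ for the concentration $x$
(µM) of the feedback protein, with time in hours and external growth
context $(\lambda, \delta)$: the specific growth rate and a first-order
molecular decay rate, combined into the dilution-dominated loss
$\lambda + \delta$.

* **Autoactivator**: $\dot x = b + \beta\,x^n/(K^n + x^n) - (\lambda+\delta)x$.
* **Protease switch**: same production; the loss becomes
  $\lambda + \delta + \delta_p/(1 + (s/s_0)^{h_p})$, a protease whose
  activity the signal represses.
* **Two-component switch**: kinase and TF share the autoregulated operon
  ($K = \rho x$). With fast phosphorylation/dephosphorylation the
  phosphorylated fraction is $p = aK/(aK + k_{deph}/k_{phos})$ with
  $a(s) = s/(s + k_{act})$, the active dimer is $D = (p x)^2/K_D$, and the
  promoter reads $D$ through the same Hill form. Because both the kinase
  and the TF concentrations dilute as $1/\lambda$, the onset signal scales
  as $(\lambda+\delta)^2$ — the quadratic sensitivity law.
* **lac switch**: LacY ($x = Y$) imports the inducer; the intracellular
  inducer is at quasi-steady state,
  $\tau = \alpha_{imp} Y c / (\lambda + \delta + k_{hyd} z Y)$, and
  production is $q_h(\lambda)\,[\ell + (1-\ell)\,\tau^{n_\tau}/(\tau^{n_\tau}
  + K_\tau^{n_\tau})]$ with leak fraction $\ell$.

Quasi-steady-state reduction is exact at fixed points, so the scalar
steady-state machinery and the full un-reduced ODEs (`integrate_model()`,
the oracle) agree there; for the two-component circuit the full model keeps
phosphorylation at finite rates, so its fixed points differ from the
reduction by terms of order $(\lambda+\delta)/k_{deph} \approx 1\%$ at the
defaults. Equivalence tests therefore use a 2% tolerance.

## The growth law of full induction

The full-induction expression of a catabolic operon is a *level* (µM), not
a rate: it is what a fluorescence-per-volume measurement reports, and the
measured zero-growth intercept of the lac C-line is of order
$y_0 \approx 70$ µM. The production rate at full induction is therefore
$q_h(\lambda) = y_h(\lambda)\,(\lambda+\delta)$, and the package offers
four growth-law modes for $y_h$:

| mode | level $y_h(\lambda)$ | scenario |
|---|---|---|
| `constant_activity` | $q_0/(\lambda+\delta)$ | constant production rate: CRP activity clamped (the cAMP-locked mutant) |
| `constant_level` | $y_{level}$ | hypothetical growth-rate-independent expression |
| `c_line` | $y_0 (1 - \lambda/\lambda_*)$ | catabolic (CRP) growth law under nutrient modulation |
| `r_line` | $\kappa\,\lambda$ | behaviour under translation inhibition |

This distinction matters quantitatively. Nondimensionalizing the lac
reduction shows that the saddle-node boundaries in external inducer
concentration satisfy

$$ c^\ast \;=\; G \cdot \frac{K_\tau\,(\lambda+\delta)^2}
   {\alpha_{imp}\, q_h(\lambda)} $$

with $G$ a pure number depending only on the leak and the induction Hill
coefficient ($G_{low} = 2.00$, $G_{high} = 15.8$, geometric-mean
$\Gamma = 5.62$ at the defaults $\ell = 10^{-3}$, $n_\tau = 2$; the
grouping is exactly growth-rate invariant, which the package verifies
numerically to five digits). Hence:

* `constant_activity` gives $c^\ast \propto (\lambda+\delta)^2$ — the
  quadratic law with a plateau once the doubling time reaches the molecular
  half-life (48 h by default);
* `c_line` gives $c^\ast \propto \lambda/(1 - \lambda/\lambda_*)$ at
  $\delta = 0$, which equals the inverse Monod function
  $K_s \lambda/(\lambda_{max} - \lambda)$ *exactly* when
  $\lambda_* = \lambda_{max}$ and
  $y_0 = \Gamma K_\tau \lambda_{max} / (\alpha_{imp} K_s)$;
* `r_line` gives $c^\ast \propto (\lambda+\delta)/\lambda$ — independent of
  growth rate up to the small $\delta/\lambda$ correction, with *no*
  additional rescaling of $K_\tau$ required. A `ktau_scaling` exponent is
  exposed for exploration but defaults to 0 in both modulation modes.

`calibrate_cline()` runs at $\delta = 0$ because the optimal-tracking
statement is exact only in the stable-molecule idealization: with
$\delta = \ln 2/48$ h$^{-1}$ the $(1 + \delta/\lambda)$ factor alone forces
a sup-norm log deviation of roughly 8% at the slow end of the range
($\lambda = 0.1\,\lambda_{max}$, where $\delta/\lambda \approx 0.2$). The
calibration profiles the scale $y_0$ analytically (it shifts the whole
curve on the log axis) and searches only $\lambda_*$ numerically.

## Default parameter values

The abstract circuits' defaults were chosen once to reproduce the
qualitative phase-diagram topology of their archetypes, before any
quantitative output was computed, and have not been revisited: the
autoactivator is bistable for doubling times between roughly 5 and 46
hours; the protease switch stays bistable at arbitrarily long doubling
times for intermediate signal but resolves to off/on at weak/strong signal;
the two-component switch remains bistable at arbitrarily strong signal at
fast growth (phospho-saturation) while its onset falls roughly
quadratically with doubling time. The saturation feature is not cosmetic:
with the onset at $T = 1$ h sitting near the activation knee, the measured
10-fold ratio of onset signals ($T = 1$ vs $10$ h) is ~90, larger than the
71 the asymptotic $(\lambda+\delta)^2$ law alone would give at a 48-h
half-life.

The lac defaults are anchored to measured quantities: molecular half-life
48 h; leak $10^{-3}$, placing the off-state/unstable expression at
0.1–0.2 µM (one to three hundred molecules at 2.5 fL) for 1–2 h doubling
times; $K_\tau = 10$ µM and $\alpha_{imp} = 0.01$ µM$^{-1}$h$^{-1}$ per µM
LacY, which put the critical TMG near 56 µM at a 1-h doubling time, the
lower bistable edge near 5 µM at glycerol-like growth, and the calibrated
C-line intercept at $y_0 \approx 46$ µM — the same order as the measured
≈70 µM. Glucose Monod parameters are solved exactly from the two single-cell
anchors (1.06 doublings/h at 11.1 mM, 0.19 at 2 µM); lactose takes
$\lambda_{max} = 0.72$ h$^{-1}$ with $K_s$ set so that saturating lactose
(550 µM) matches growth on 50 µM glucose, the observed preference
crossover. The lactose $K_s$ is a calibration, not a validation.

# Phase diagrams and critical curves

Classification counts stable fixed points by a sign-change scan of the
reduced equation on a 2,000-point log grid spanning nine decades below
1.5× the maximal production/dilution balance (no root can lie above it).
Roots alternate stable/unstable because production is bounded and positive
at $x = 0$; an exact boundary root at zero (no basal production) is handled
separately. `find_fixed_points()` refines roots by bisection to
$|f| < 10^{-10}$ and merges saddle-node coincidences closer than $10^{-6}$
of the scan scale. Boundaries in signal are located by a 400-point log scan
bracketing bisection to a $10^{-4}$ relative tolerance; an infinite upper
boundary means the system is bistable up to the top of the scan range. The
centre of the bistable region is the geometric mean of the two saddle-node
signals — the log-axis midpoint, matching how the phase diagrams are drawn.
For monostable points, off/on is decided against the geometric mean of the
basal and full expression scales (the promoter half-max replaces a zero
basal scale); the underlying experimental literature never needs this
discriminator because measured states are far from it.

`scaling_exponent()` is a plain OLS slope in log10–log10; the Bayesian
errors-in-variables machinery is used when per-point errors exist.

# Bulk fitting

**Hill fits.** The four-parameter response
$\alpha(c) = b\,(1 + f (c/k)^m)/(1 + (c/k)^m)$ is fitted by weighted least
squares in log-activity space (weights $(\alpha_i/\sigma_i)^2$), with all
parameters log-transformed for positivity, $f = 1 + e^{\phi}$ to keep the
fold change above one, and multi-start over $k$ (every observed
concentration) and $m \in \{1, 2, 4\}$. A fitted fold change below 1.2
flags the threshold as unidentifiable (at $f = 1$, $k$ drops out of the
model). The relative error of $k$ is the standard error of $\log k$ and is
what feeds the slope fit as $\sigma_i$. Replicates are fitted as individual
points.

**Errors-in-variables slope.** For points $(x_i, y_i)$ with measurement SDs
$\sigma_i$ and intrinsic scatter $\sigma$, each residual is normal with
variance $\sigma^2 + \sigma_i^2$. The intercept and slope are marginalized
analytically under flat priors; the intrinsic scatter carries the scale
prior $d\sigma/\sigma$ and is optimized by bounded golden-section search on
$\log\sigma$ — the scale on which that prior is flat. This choice is not
cosmetic: the posterior *density of* $\sigma$ diverges as $\sigma \to 0$
under the scale prior, so maximizing it collapses the scatter to zero on
more than half of calibration datasets and shrinks the slope's error bar
(observed ±2SD coverage 80%); on the log scale the mode is interior,
$\hat\sigma$ is unbiased in calibration (median 0.149 at a true 0.15) and
the ±2SD interval covers the true slope in ~93% of simulations. The
posterior of the slope at $\hat\sigma$ is Gaussian with mean and SD in
closed form; tests verify both against brute-force 2-D grid integration.

# Plate-reader processing

Backgrounds are estimated per channel as the mean over a 20-point window
centred on the channel minimum (clipped at the series edges) and
subtracted. The growth segment is the longest contiguous run, before the
OD peak, of points with corrected OD in $(0.01, \mathrm{OD}_{max}/3)$ and
positive reporter signal; runs shorter than 21 points are rejected. Taking
the longest run (rather than stopping at the first violation walking back
from the peak) matters because measurement noise flickers the OD across the
$\mathrm{OD}_{max}/3$ boundary and would otherwise truncate segments to a
handful of points. Growth rates are OLS slopes of $\log_2$ OD against time
(doublings/hour). Background subtraction leaves a known small systematic at
the low-OD end of the segment — the inoculum biomass is indistinguishable
from instrument background — worth about +2% on the recovered doubling
rate at the defaults; end-to-end accuracy is therefore quoted at a few
percent even though the pure regression SE is ten times smaller.

Miller activities use $A = 1000\,s/(0.5\,\mathrm{OD}_{600})$ with $s$ the
initial OD420 slope per minute over 30 minutes, after discarding an initial
decreasing phase of up to one hour (cut at the first local minimum within
that hour). Promoter activity is $\alpha = A\lambda$ — the turnover of a
stable enzyme in balanced growth is dilution. The fluorimetry estimate
slides a 21-point window across the segment, fits log OD and log
fluorescence against time in each window, and combines windows by
inverse-variance weights; overlapping windows are correlated, so the
combined SEs are indicative relative weights rather than exact standard
errors.

# Single-cell lineage analysis

Growth rates are OLS slopes of $\log_2$(length); cells observed for fewer
than 10 frames are filtered. Traces classify as induced/uninduced when at
least 95% / at most 5% of fluorescence frames exceed 250 molecules; the
remainder are mixed and discarded. Volumes assume a spherocylinder with the
per-condition mean diameter (per-frame diameters are too noisy).
Instantaneous growth, volumic production (fluorophore increment per µm³
per hour) and concentration come from centred rolling regressions of
window 5 frames, computed strictly within cells so divisions cannot
produce rate spikes; concentration is additionally smoothed over the same
window. Photobleaching at continuous rate $\beta$ is corrected by the
steady-state relation $c = c_u(1 + \beta/\lambda)$.

Switch detection classifies each frame into quadrants of
(log production, log concentration) against a common natural-log threshold
of 5.5. An on-switch is a passage from the low/low to the high/high
quadrant, timed at the interpolated moment production crossed the
threshold; off-switches mirror this; excursions in which production crosses
but concentration never follows are not events. A stable quadrant must
persist for two consecutive fluorescence frames to count — single noisy
frames cannot fake a completed switch. Because switches span several cell
cycles, detection operates on lineages: the parent's estimates are
prepended and the frame-wise average of the daughters' (truncated at the
shorter daughter) appended, or — for mother-machine channels — the whole
mother line is concatenated.

# The synthetic-data generators

The plate generator produces exponential growth with a lag and an abrupt
saturation at substrate exhaustion (on a single carbon source whose Monod
constant is far below the feed concentration, the rate is constant until
the substrate runs out; a logistic shape would depress the in-segment rate
by up to a third). The reporter channel is OD times the steady-state
expression level set by the condition's Hill induction curve (level =
activity / doubling rate); instrument backgrounds are added and
multiplicative log-normal noise (OD CV 2%, signal CV 5%) applied per
point. Slow conditions are monitored longer so that every culture passes
through mid-exponential — the role the protocol's dilution-factor/delay
combinations play on a real plate.

The lineage generator emulates mother-machine experiments on
glucose/lactose mixtures. Each channel carries an Ornstein–Uhlenbeck
fluctuation $\eta$ on log growth rate (mean reversion 0.5 h$^{-1}$,
stationary CV 0.3); the cell grows at the Monod rate of its currently
usable sugar (glucose when uninduced; the faster of the two sugars when
induced) times $e^{\eta}$. The lac ODE is driven by the instantaneous rate
through dilution, while the growth-law expression level is evaluated at the
nutrient-set base rate — catabolic regulation tracks nutrient quality, not
fast single-cell noise. This split is what makes the switching mechanism
cleanly growth-coupled: dips in growth rate lower dilution, intracellular
inducer and LacY rise, and the cell can cross the unstable manifold; spikes
drive the reverse. Division occurs at a threshold length (4 µm) with a
±2.5% asymmetry and binomial partitioning of fluorophores; lengths are
observed every 3 minutes (1% noise), fluorescence every 9 minutes (2%
noise) with 4.4% of fluorophores bleached per exposure. The OU parameters
were calibrated once so that the fraction of cells switching near the
preference tie matches the observed few-percent rates (1–3% per condition);
the mean-reversion and CV first tried (2 h$^{-1}$, 0.2) produce *no*
switches at all in over a thousand lineage-hours, because fluctuations much
shorter than the switch's integration time average out.

Ground truth records the noise-free concentration and volumic-production
series of every mother line and the completed switch events obtained by
applying the same quadrant rule to that noise-free series; generator and
detector share one unit convention (molecules per µm³, and per hour), so
the e$^{5.5}$ threshold is meaningful for both.

What the generators deliberately omit: imaging artefacts (point-spread,
segmentation error), expression bursting (switching here is driven purely
by growth fluctuations), mother-machine nutrient gradients (absent in
flow-through devices), and the allolactose/LacZ hydrolysis network beyond a
configurable first-order removal term. Passing tests on these data
therefore validate the estimators and the GCS logic, not microscopy
robustness.

# Problem sizes used by the test-suite

The suite runs end to end in a few minutes: oracle equivalence uses 100
random parameterizations (25 per circuit) with three initial conditions
each, extended adaptively when a draw lands near a saddle-node; the slope
posterior is checked against 321² grid integrations on 20 datasets and
calibrated over 500 simulations; plate recovery uses two to eight
conditions at eight inducer concentrations; lineage benchmarks use 40
channels for 30 hours at the coexistence conditions (32 µM glucose for
on-switches, 110 µM with induced ancestry for off-switches). These sizes
were chosen as the smallest that make the statistical assertions sharp.

# Known limitations

* The supplementary derivations of the original circuits are not public;
  the abstract presets are principled stand-ins whose topology, not
  parameter values, carries the claims.
* The C-line/inverse-Monod equivalence is exact only for $\delta = 0$;
  with a 48-h half-life tracking degrades to ~8% at the slowest growth
  rates considered.
* The quadrant detector's thresholds are shared constants between generator
  and analysis; applying it to real data requires re-deriving the
  threshold from the bimodal marginals, as the original analysis does.
* `run_pipeline()` covers the common batch workflows; it is a thin
  orchestration layer over the exported functions, which remain the
  primary interface.
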