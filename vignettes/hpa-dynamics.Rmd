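---
title: "Modelling glucocorticoid dynamics and receptor-mediated feedback with hpaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucocorticoid dynamics and receptor-mediated feedback with hpaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(hpaxis)
```

## The model

`hpaxis` simulates the hypothalamic–pituitary–adrenal (HPA) axis as a small
deterministic dynamical system. An external demand

$$p(t) = B + b\,\alpha\,e^{-\alpha t}$$

drives the cascade: a constant baseline energetic requirement $B$ plus an
acute stressor whose total magnitude is $b$ (the pulse integrates to $b$)
and whose persistence time scale is $1/\alpha$ minutes. The demand
stimulates hypothalamic CRH ($C$), CRH stimulates pituitary ACTH ($A$), and
ACTH stimulates adrenal glucocorticoid (GC) release into plasma ($O$):

$$
\begin{aligned}
dC/dt &= p(t) - b_C C - k_{CG} (O_G + D_G) - k_{CM} O_M\\
dA/dt &= k_A C - b_A A - k_{AG} (O_G + D_G) - k_{AM} O_M\\
dO/dt &= k_O A - b_O O - (k_G O G - k_{-G} O_G) - (k_M O M - k_{-M} O_M)
\end{aligned}
$$

Free GC binds the glucocorticoid receptor (GR, free pool $G$) and the
mineralocorticoid receptor (MR, $M$) in HPA tissue by mass action,

$$dO_G/dt = k_G O G - k_{-G} O_G, \qquad dO_M/dt = k_M O M - k_{-M} O_M,$$

and the occupied receptors close the loop: the $k_{CG}, k_{CM}, k_{AG},
k_{AM}$ terms above are the negative feedback that returns the axis to
baseline. All four feedback constants share one value ($k_{fb} = 0.1$) by
default, so the two receptor types differ only in abundance
($G_{tot}, M_{tot}$) and affinity. At chemical equilibrium the bound
complex follows the saturation form

$$O_G = \frac{G_{tot}\, O}{O + K_G}, \qquad K_G = k_{-G}/k_G,$$

and the GC–GR complex $O_G$ is the model's readout of the GC-mediated
physiological response: it is what the hormone *does*, as opposed to what a
plasma sample *shows*.

Two exogenous compartments ($D$, $D_G$) carry dexamethasone (DEX), a
synthetic GR agonist used in field protocols to probe maximal feedback
capacity. A DEX bolus enters $D$, binds GR with the same kinetics as GC,
contributes to feedback through $D_G$, degrades at the GC clearance rate,
and is invisible to `measure()` — a plasma GC assay does not read DEX.
An ACTH challenge is a bolus added to $A$.

### What the simulation integrates, and what the closed form is for

The simulation always integrates the kinetic binding equations, so receptor
conservation ($G + O_G + D_G = G_{tot}$, $M + O_M = M_{tot}$) and binding
transients are explicit; the closed-form occupancy is exposed separately
(`equilibrium_binding()`) and doubles as a consistency oracle — integrating
the kinetics to stationarity must land on it, and the test suite checks
that it does to $10^{-4}$ relative over a grid of ligand levels and
receptor abundances.

### Numerical choices

* Integration uses `deSolve::lsoda` with `rtol = 1e-8`, `atol = 1e-10`;
  injection events are applied as exact jumps with a hard integrator
  restart at the event time, so the discontinuity is never smoothed.
  A fixed-step RK4 path (`method = "rk4"`) exists purely as a
  cross-check and agrees with the adaptive solution to better than
  $10^{-4}$ relative on plasma GC.
* Simulations start from the baseline steady state (`baseline_state()`),
  found by reducing the stationarity conditions to a single scalar root in
  $O$ and polishing with `uniroot`; otherwise "baseline" samples would
  measure an initialisation transient.
* Concentrations are physical, so the right-hand side clamps outflow from
  an empty pool: a non-positive component with a negative derivative gets
  derivative zero. With the default calibration the clamp never engages
  (the axis stays interior); it exists as a guard for extreme parameter
  draws. A practical consequence worth knowing: because the feedback terms
  are subtractive, parameter sets with `k_fb * (G_tot + M_tot)` approaching
  `B` can pin CRH/ACTH at zero and then integrate slowly — the shipped
  defaults keep a comfortable margin over the whole default sweep range.
* Trajectories are stored on a 0.1-min output grid by default;
  `measure()` interpolates linearly.

## The default calibration

The package's defaults are one fixed reference parameterisation, chosen
once to express the qualitative physiology the model is built around, in
arbitrary concentration units with time in minutes:

```{r}
hpa_params()
```

The calibration targets, all of which the test suite asserts:

* baseline plasma GC ≈ 2.6 units with GR mostly unbound (occupancy ≈ 0.3),
  and an ~11-fold GC peak 20–25 min after stressor onset at which GR
  approaches saturation (occupancy ≈ 0.83) — GR is the low-affinity,
  acute-response receptor ($K_G = 6$), MR the high-affinity one
  ($K_M = 0.2$), saturated already at baseline;
* the four standard sampling classes order as
  baseline < post-DEX < stress-induced < post-ACTH;
* receptor binding is slow relative to hormone clearance (GR complex
  half-life ≈ 2 h), so occupancy — and with it feedback — lags the plasma
  GC rise, as expected for genomic receptor action. This lag matters: it
  is what makes feedback clip the GC peak hardest in high-GR individuals,
  reproducing the later peaks and longer elevation of low-GR individuals.
  In fast-equilibrium regimes the receptor pool instead acts as a buffer
  and the peak-timing pattern reverses.

The injection protocol mirrors standard field endocrinology: stressor at
minute 0, samples at ~0–3 min (baseline) and 20–30 min (stress-induced),
DEX right after the stress-induced sample (minute 30, sampled 60–80 min),
and an ACTH challenge at minute 80 (sampled at 100 min). Doses (150 DEX,
2500 ACTH in model units) were calibrated together with the parameters;
challenge doses are deliberately supraphysiological, as in the protocols
they emulate.

```{r}
traj <- simulate_response(hpa_params(), events = default_events(),
                          horizon = 180)
traj
measure(traj)
```

```{r, fig.alt = "GC and GC-GR trajectories for the default protocol"}
plot(traj$time, traj$O, type = "l", xlab = "time (min)",
     ylab = "concentration", ylim = c(0, max(traj$O)))
lines(traj$time, traj$O_G * 10, lty = 2)
abline(v = c(30, 80), col = "grey70")
legend("topright", c("plasma GC (O)", "GC-GR complex (x10)"),
       lty = c(1, 2), bty = "n")
```

## Fitting

`fit_hpa()` maximises a Gaussian log-likelihood by Nelder–Mead simplex
search over the free parameters of a `parameter_mask()`, on the log scale
so positivity holds by construction (reflection 1, expansion 2,
contraction 0.5, shrink 0.5 — `stats::optim` defaults — with
`reltol = 1e-8` and up to 5000 iterations; one-parameter fits use bounded
Brent search instead, where a simplex degenerates). The residual SD is
profiled at its MLE by default, or fixed via `sigma`.

Design decisions a user should know:

* **Error scale.** The likelihood's distributional form is a package
  decision: iid Gaussian on the raw GC scale by default, with
  `log_scale = TRUE` switching to Gaussian residuals on log GC. For
  GC-like data (right-skewed, multiplicative error) the log scale is
  usually right, and it matters for identifiability here: on the raw scale
  the large stress-induced values dominate the sum of squares, while most
  of the information about receptor abundance sits in the small baseline
  and post-DEX values. The parameter-recovery study in the test suite
  therefore fits on the log scale.
* **Identifiability.** The full 11-parameter set the model exposes is not
  identifiable from a four-class profile. The recommended masks are
  `c("G_tot", "k_O", "b_O")` (abundance, production, clearance) for pooled
  profiles, and `free = "G_tot"` per individual
  (`fit_gr_per_individual()`) when shared parameters are held at
  reference values — the mode for inferring relative GR abundance from GC
  profiles alone. Masks freeing more than six parameters are flagged on
  the fit object.
* **Starting values.** `visual_start()` replaces fitting "by eye" with a
  deterministic heuristic: the stressor scale from the relative
  stress-minus-baseline contrast, clearance from the log-decline between
  the stress-induced and post-DEX class means, production from the
  baseline magnitude. The rules are ratio-based, so rescaling the data
  rescales production proportionally and leaves rates untouched.
* **Multi-start.** `n_starts > 1` jitters the starts log-normally with a
  fixed seed; results are bit-reproducible for a given seed.

```{r}
data <- read_observations(fixture_profiles_path())
fit <- fit_hpa(data, parameter_mask(free = c("G_tot", "k_O", "b_O"),
                                    start = visual_start(data)),
               log_scale = TRUE)
fit
```

## The three prediction analyses

**GR sweeps** (`sweep_gr()`): re-simulate the full protocol over a 10-fold
log-spaced grid of `G_tot` (9 points) around the reference value. GC
declines with GR at every sampling class, and the decline is steepest
where GC is highest (post-ACTH, then stress-induced, then post-DEX, then
baseline) — receptor feedback has the most hormone to act on at high GC.

**Stressor sweeps** (`sweep_stressor()`, `sensitivity_index()`): factorial
`G_tot` × `b` simulation of the pure stress response. The
physiological-response range (max − min of $O_G$) grows with stressor
intensity but saturates as occupancy approaches `G_tot`; low-GR
individuals saturate at lower intensities. The index is the ratio of the
response range at the highest vs the middle intensity of the 6-point,
8-fold default grid: near 1 means saturated (no headroom to scale the
response — low endocrine flexibility), near the intensity ratio means
linear.

**Association analysis** (`association_analysis()`,
`stressor_association()`): simulate a population varying only in `G_tot`
(log-normal, default CV 0.5), sample plasma GC at 0/30/120 min, and
correlate it with peak $O_G$. Because GR raises the response while
lowering plasma GC, the among-individual rank correlation at a single
timepoint can be strongly negative even though within any individual the
GC-to-response mapping is strictly increasing — the package asserts both
signs in one test. Spearman correlations are primary (the relations are
monotone but nonlinear); Pearson is also reported.

```{r}
sweep_gr(hpa_params(), default_gr_grid(n_gr = 5))[, 1:5]
```

## Synthetic populations

`generate_population()` is the package's stand-in for the empirical
datasets this class of model is fitted to (multi-timepoint GC profiles
from wild or captive birds). It emulates their *structure*, not any
particular study's biology:

* among-individual GR variation: `G_tot` log-normal with median at the
  reference value and CV 0.5 — right-skewed and positive, as expression
  data are;
* one sample per class per individual, at a time drawn uniformly within
  the class window (0–3, 20–30, 60–80, 100 min), since field samples are
  never taken at identical times;
* multiplicative log-normal measurement noise (default CV 10%);
* a `gr_expression` covariate that is deliberately a *noisy proxy* of true
  `G_tot` (log-normal proportionality factor, CV 20%), so that
  observed-vs-predicted comparisons face realistic attenuation rather
  than an implausibly clean receptor measurement.

What passing tests on these data do **not** show: robustness to assay
floor/ceiling effects, circadian baseline drift, individual differences in
stressor perception (`b` is shared unless `b_cv > 0`), or model
misspecification — the generator and the fitted model share the same
equations, so recovery tests validate the estimation machinery, not the
model's adequacy for any real dataset.

## Problem sizes and reproducibility

The shipped studies use deliberately moderate sizes, chosen as the scale
at which the questions are answerable and the whole suite stays quick on a
laptop: 9-point GR grids, 6-point stressor grids, 200 individuals for the
association analysis, and 20 seeded replicates of 30 individuals × 4
classes for parameter recovery (median |relative error| of each of
`G_tot`, `k_O`, `b_O` stays under 20% at 5% measurement noise, and
shrinks as noise goes to zero). Every stochastic step takes an explicit
integer seed; rerunning any pipeline stage with the same seed reproduces
its outputs byte for byte.

## Known limitations

* Feedback is subtractive (zeroth order in CRH/ACTH), literal to the model
  equations; it admits regimes where production pins at zero (see the
  clamp note above).
* No pre-binding regulation (CBG, 11β-HSD), no FKBP5-style affinity
  modulation, no adrenal self-inhibition or hippocampal input, no
  circadian/ultradian baseline, no stochastic dynamics — all outside the
  model's scope.
* MR effects enter only through feedback and a fixed pool; tissue-specific
  MR action is not represented.
* Observed GC maps one-to-one onto model $O$; there is no observation
  scale parameter unless you free production/clearance jointly.
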