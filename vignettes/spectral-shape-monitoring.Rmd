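---
title: "Spectral-shape models for cell-concentration monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-shape models for cell-concentration monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speccult)
```

## The measurement problem

Suspension cell cultures (T-lymphoblast lines such as CEM, yeasts such as
*Candida albicans*) need frequent concentration checks during expansion.
Automated image-based counters are accurate but sample only ~10 µL, which is
poorly representative of the flask and introduces a sampling dispersion of
about 10%; they also cannot run in-line in a closed loop. White-light
transmission spectroscopy through a cuvette is contactless, uses a far larger
interrogated volume, and produces a full spectrum whose *shape* — not just
its height at one wavelength — carries concentration information. Shape
information is what makes it possible to measure two co-cultured species at
once, which no single-wavelength Beer–Lambert readout can do.

`speccult` implements the full chain: preprocessing of measured spectra,
calibration of a parametric shape model per species, inversion of spectra for
one or several concentrations, and the accuracy analyses (bias/dispersion,
leave-sets-out cross-validation, growth-curve fitting, crosstalk planes). A
synthetic generator emulates the statistical structure of the measurement
chain so every analysis can be exercised, end to end, against a known ground
truth.

## The model

Working in percent absorption relative to a blank-medium cuvette,
$Abs(\lambda) = 100\,(1 - T(\lambda))$, a species' spectrum over the
330–860 nm window is described by a small sum of Gaussians whose
coefficients are functions of the cell concentration $C$:

$$Abs(\lambda, C) \;=\; \sum_{i} a_i(C)\,
  \exp\!\left[-\left(\frac{\lambda - b_i(C)}{c_i(C)}\right)^{2}\right].$$

The default is two components: a concentration-sensitive Gaussian and a
near-constant "baseline" Gaussian rising toward the near infrared. Each
coefficient is a *sub-function* of concentration from one of four families:

* **constant** $f(C) = k$;
* **Beer–Lambert amplitude** $f(C) = 100\,(1 - 10^{-p_1 C})$ — the
  saturating amplitude law an absorbing suspension follows;
* **power** $f(C) = p_1 C^{p_2}$ — an empirical width law, not tied to a
  specific light–matter interaction;
* **log-linear** $f(C) = p_1 + p_2 \log_{10} C$.

Two calibrated models ship with the package:

```{r}
cem_reference_model()
ca_reference_model()
```

The CEM model is monotone increasing in $C$ at every wavelength, so
single-species inversion is well posed. The yeast model's first Gaussian has
a log-linear center far below the window at in-range concentrations; it acts
as a broad sloping background, and the published parameters are used exactly
as calibrated rather than "corrected". Because its log-linear coefficients
are meaningless as $C \to 0$, each model carries a *concentration floor*
(default $10^4$ cells/mL) below which the species is treated as absent in
mixtures — this lets a two-species fit degrade gracefully to one species.

Mixtures follow from optical-density additivity: absorbances of independent
absorbers add, transmittances multiply, hence in percent-absorption terms

$$Abs_{mix} = 100\Big(1 - \prod_i \big(1 - Abs_i/100\big)\Big),$$

implemented by `mix_absorption_spectra()` and checked in the test suite
against the explicit $-\log_{10} T$ summation to $10^{-10}$ percentage
points.

## Calibration

`calibrate_species_model()` reproduces the two-stage procedure:

1. **Free fits.** Every spectrum in the dilution series is fitted with
   $n$ free Gaussians (`fit_free_gaussians()`), by Levenberg–Marquardt.
2. **Iterated constant-fixing** (`iterate_constant_fixing()`). For each
   still-free coefficient a spread statistic is computed across the series —
   the coefficient of variation for amplitudes and widths, and the standard
   deviation divided by the window span for centers (centers have an
   arbitrary offset, so a CV is meaningless). The least-spread coefficient,
   if below the threshold (default 0.05), is fixed at its across-series mean
   and the fits repeat — one coefficient per iteration, preserving a full
   audit trail. A user can force coefficients constant to reproduce a manual
   decision.
3. **Sub-function fitting** (`fit_subfunction_families()`). Each remaining
   free coefficient's trend against concentration is fitted with every
   candidate family.
4. **Global refinement** (`minimize_global_surface()`). All sub-function
   parameters are then adjusted jointly by Nelder–Mead simplex on
   $\sum_\lambda \sum_C (Abs_{model} - Abs_{obs})^2$, uniformly weighted,
   started from the stage-3 parameters. The simplex never returns a worse
   objective than its start.

```{r, eval = FALSE}
set0 <- generate_calibration_set(cem_reference_model(), noise = noise_free())
cal <- calibrate_species_model(set0, name = "CEM")
cal$structure      # which coefficients are constant vs free
cal$final_params   # jointly refined parameters
```

### Numerical choices

* **Gaussian-fit starts.** Broad overlapping Gaussians produce local optima
  whose residuals are almost as small as the global one ($R^2 > 0.9999$ with
  entirely wrong parameters). A single starting point is therefore not
  reliable; the fitter tries a fixed list of seven deterministic
  initializations (centroid-based, peak-based, close-center straddles) and
  keeps the lowest-SSE solution. Inside the calibration loop each spectrum
  additionally warm-starts from its neighbour's solution and from its own
  previous-iteration solution, which keeps the whole dilution series in one
  consistent basin. Everything is deterministic: same data, same result.
* **Family selection.** Raw $R^2$ cannot prefer a constant over a
  two-parameter family — any extra parameter fitted to noise raises $R^2$.
  Selection therefore uses small-sample corrected AIC computed from the
  residual sum of squares; exact ties go to the family with fewest
  parameters. Per-family $R^2$ values are reported for inspection.
* **Simplex tolerances.** Relative objective tolerance $10^{-9}$, at most
  $10^4$ evaluations, parameters scaled by their starting magnitudes.
  Invalid parameter regions (non-positive widths or rate constants) return a
  large penalty rather than an error so the simplex can retreat.
* **Component identity.** After the first free pass, components are
  relabelled so the amplitude most correlated with concentration is
  component 1; exact spread ties during fixing resolve in coefficient order
  $(a_1, b_1, c_1, a_2, \ldots)$, which on noiseless data fixes the
  concentration-sensitive Gaussian's center first.

## Inversion

`estimate_concentration()` minimizes the squared distance between the model
and a measured spectrum over $C$: a 200-point log-spaced scan over
$[C_{min}/2,\, 2\,C_{max}]$ followed by golden-section refinement (relative
tolerance $10^{-6}$). Estimates at a search bound are flagged `at_bound`
rather than silently extrapolated.

`estimate_mixture_concentrations()` generalizes this to $n$ species under
the mixture law: a coarse log grid over the product of ranges (15
points/axis, each axis augmented with an "absent" point), simplex refinement
in log-concentration space from the best three grid points *and* from the
best point of every species-absent hyperplane. Among fits whose SSE differs
by less than the solvers' numerical resolution (a threshold scaled to the
spectrum energy), the smallest total concentration wins — parsimony for
non-identifiable cases. Species below their floor are reported
`below_floor`; a residual surface flat over the whole grid is
`not_converged`.

## Accuracy machinery

* `compute_bias()` — intercept of the least-squares line $Y = X + Bias$
  through (counter, calculated) pairs, i.e. `mean(calc - counter)`;
  positive means overestimation.
* `compute_dispersion()` — RMS residual about that line, a modified standard
  deviation. `accuracy_report()` scales it by a *center* concentration,
  defined here as the midpoint of the calibrated range ($5.5\times10^5$
  cells/mL for the CEM model); the divisor is configurable since other
  center conventions change the percentage by ~10% relatively.
* `cross_validate()` — for every $k$-subset of the experimental sets,
  refits the template model's parameters on the pooled model sets (the
  structure stays fixed; all parameters are refit, since a held-out
  evaluation must re-estimate everything the data can move), inverts the
  held-out spectra and reports per-combination and average bias/dispersion.
* `fit_growth_curve()` — exponential fit by linear regression of
  $\ln C$ on $t$ (closed-form, deterministic; a direct nonlinear fit would
  weight large concentrations more without changing noise-free results),
  doubling time $\ln 2 / k$, and RMS dispersion about the fit over the same
  window used for fitting.
* `fit_crosstalk_planes()` — per species, OLS of calculated on all true
  concentrations. Own-species slope 1 and cross slopes 0 mean perfect
  deconvolution; non-zero cross slopes quantify leakage between similarly
  shaped spectra.

## The synthetic generator

`generate_calibration_set()`, `generate_growth_series()` and
`generate_mixture_set()` emulate the measurement chain's statistical
structure:

* **Cuvette variability** — disposable cuvettes differ optically; across
  100 cuvettes the absorption at 600 nm spreads with a full width at half
  maximum of ±2.5%, i.e. a multiplicative factor
  $g \sim N(1, 0.0106)$ ($0.0106 = 0.025 / 2.355$) per cuvette. The spread
  is modelled as multiplicative because cuvette optics scale transmitted
  intensity; a flag (`scale_baseline`) controls whether the baseline
  component scales too (default yes — the cuvette sits in the whole optical
  path). Via the model's concentration sensitivity, 2.5 percentage points at
  600 nm at mid-range corresponds to about $3.8\times10^4$ cells/mL
  (`concentration_equivalent_of_absorption_change()`).
* **Detector noise** — i.i.d. $N(0, 0.2)$ percentage points per wavelength
  (no wavelength correlation is modelled).
* **Counter dispersion** — the *reported* label is
  $C_{true}(1 + N(0, 0.10))$: it models the reference method's sampling
  error, so it perturbs the label, never the spectrum. Ground truth is
  always stored separately so recovery tests have an oracle.
* **Growth series** — piecewise-exponential trajectories measured in a
  single cuvette, so the cuvette factor is forced to 1; the default
  30-h sampling schedule (hourly 0–4 h, half-hourly 4–11 h, two-hourly
  21–30 h, 25 points) mimics an attended experiment with no overnight
  samples.

Default study conditions are 8 concentrations log-spaced over
$10^5$–$10^6$ cells/mL per calibration set (a weekly dilution series) and
$0.5$–$4\times10^6$ cells/mL for the yeast model. With the default noise
model, leave-3-sets-out cross-validation lands at a dispersion of roughly
7–8% of the center concentration — dominated by the counter's 10% label
noise over the in-range concentrations, with a smaller cuvette contribution.

What the generator does *not* emulate: wavelength-correlated drifts of the
lamp, lag/stationary growth phases, spectral signatures of dead cells or
debris, and any systematic week-to-week drift of the biology. Passing tests
on synthetic data therefore demonstrate the correctness and conditioning of
the algorithms under the stated noise structure, not the field accuracy of a
particular instrument.

## Problem sizes used in the shipped tests

Synthetic spectra are generated on 1–5 nm grids (a 0.22 nm instrument step
carries no extra information for Gaussians hundreds of nm wide — estimates
are stable under factor-2 subsampling, which the suite checks). The
cross-validation studies use 8 sets of 8 spectra with $k = 5$ (56
combinations); the noise-realism study repeats that over ten seeds with the
refinement tolerance at $10^{-7}$, which changes recovered parameters by
well under the noise level. The two-species study inverts a 450-point grid
(75 CEM levels × 6 yeast levels).

## Known limitations

* The quality filter (free two-Gaussian fit $R^2 \ge 0.9$) is a documented
  heuristic; it flags grossly malformed spectra, not subtle instrumental
  artifacts.
* Calibrated parameters carry no uncertainty quantification.
* Mixtures of species with very similar spectral shapes are intrinsically
  ill-conditioned; the crosstalk planes quantify, but cannot remove, that
  leakage.
* Deuterium-lamp artifact masks default to the hydrogen Balmer lines
  (484–488, 654–658 nm) with linear interpolation across the (narrow)
  masks; instruments differ, so masks are configuration, not constants.
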