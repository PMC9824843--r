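---
title: "Modelling and in-line monitoring of lignosulphonate methylolation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and in-line monitoring of lignosulphonate methylolation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylolation)
```

## The chemistry being modelled

Lignosulphonates (LS) are sulfonated lignins recovered from sulfite
pulping. Their aromatic rings carry few reactive positions — hardwood
(syringyl-rich) lignin fewer still than softwood (guaiacyl-rich) — which
limits their direct use as phenol substitutes in adhesive resins.
Methylolation with formaldehyde under alkaline conditions
(Lederer–Manasse reaction) adds hydroxymethyl groups to the free ring
positions and is the standard activation step. The package models a batch
methylolation run monitored two ways: hourly off-line assays of free
formaldehyde and of type I+II phenolic hydroxyl groups, and continuous
in-line visible spectra from an immersion probe.

## Kinetic model

Free formaldehyde is consumed by a second-order reaction with the
reactive phenolic pool, optionally plus a secondary channel quadratic in
formaldehyde (Cannizzaro-type self-reaction and similar losses):

$$-\frac{d[F]}{dt} = k_1(T)\,[POH]\,[F] + k_2(T)\,[F]^2$$

Only part of the phenolic groups can react at all:
$[POH]_{reactive} = [POH]_0\,(1 - f_{nr})$ where $f_{nr}$ is the
non-reactive fraction; the remainder is carried as a constant offset in
the observable total. Assumptions worth making explicit:

* the partition into reactive and non-reactive groups is fixed for a run
  (`reactive_pool()`), and the non-reactive remainder is chemically
  inert;
* temperature enters only through the values of $k_1, k_2$ — no
  Arrhenius law is fitted, because with one rate constant per
  temperature and assay delays of 15 min or more an activation energy
  would not be identifiable (rate constants have indeed been observed to
  order non-monotonically with temperature in this system);
* units are fixed package-wide: mol/L and hours.

With $k_2 = 0$, `simulate_trajectory()` uses the exact closed-form
solution of the unequal-concentration second-order law, switching to the
$1/(b-x) - 1/b = k_1 t$ form when $[F]_0$ equals the reactive pool to
within $10^{-10}$ relative. With $k_2 > 0$ it integrates the coupled
system with `deSolve::lsoda` at absolute tolerance $10^{-9}$ and
relative tolerance $10^{-8}$; the closed form is preferred whenever
available because it removes any step-size risk. Conservation
($x = [F]_0 - [F]_t = [POH]_{reactive} - [POH]_t$ when $k_2 = 0$) is
asserted to $10^{-9}$ mol/L by `extent()`.

## Parameter estimation

`fit_kinetics()` minimises the joint unweighted sum of squared residuals
of the simulated versus observed $[F]$ and $[POH]$ series. Both series
are weighted equally by default because both assays monitor the same
reaction with comparable (mol/L-scale) noise; per-series weights and
single-series fitting are configuration options for instruments with
very different precision. The optimiser is L-BFGS-B with bounds
$k_1 \ge 0$, $k_2 \ge 0$, $f_{nr} \in [0, 1)$, restarted from a fixed
grid ($k_1 \in \{0.1, 0.5, 1, 2, 5\}$, $k_2 \in \{0, 0.1\}$,
$f_{nr} \in \{0.5, 0.7, 0.9\}$); the lowest final SSE wins and ties go
to the smallest $k_1$, so the fit is deterministic for a given data set.
A fit whose optimum sits at the $k_1 = 0$ boundary, or whose data show
no consumption at all, is flagged degenerate rather than rejected.

On noiseless hourly series the fitter recovers the generating
parameters to well under 1 %. With realistic measurement noise
(0.005 mol/L) the dominant uncertainty is statistical, not numerical:
with duplicate hourly samples (the standard procedure takes two samples
per hour, and the generator emulates that by default) the estimator
spread of $k_1$ is under 10 % — with single samples it grows enough
that deviations beyond 15 % are no longer rare. The assay delay
(15 min between sampling and measurement, during which the aliquot
keeps reacting) biases early points most; this is why delayed data
produce biased rate constants and why the monitoring stage excludes the
first 15 min.

## UV quantification

LS content follows Beer–Lambert at 232.5 nm with
$\varepsilon = 24.5$ L g$^{-1}$ cm$^{-1}$, inverted through the
dilution train (default: 0.5 g to 1000 mL, 0.5 mL to 3.0 mL, 1 cm
path; path length is the standard quartz-cuvette value, as the
procedure leaves it implicit).

Phenolic hydroxyl groups are typed by differential ionization: types
I+II ionize in pH 12 buffer, III+IV only in 0.2 M NaOH, and the
alkaline-minus-pH 6 absorptivity difference shows two maxima near 300
and 360 nm. `ionization_difference()` locates each maximum by grid
argmax within ±20 nm of the nominal position refined by local quadratic
interpolation (the nominal positions are approximate, so a fixed-
wavelength reading would be biased by small band shifts; maxima heights
are the default, with fixed-wavelength reading available by evaluating
the returned difference spectrum directly). `phenolic_oh_content()`
maps the two heights linearly to contents. The linear coefficients of
that map are *not* universal constants: they depend on the model-
compound calibration behind the classification. The package therefore
treats them as a required configuration object and ships one documented
default set (`zakis_coefficients()`), used consistently by the
quantifier and the spectrum generator so that the stage is exactly
closed-loop testable; real-instrument work should substitute calibrated
coefficients. Conversion of a mass-percent content to reaction-medium
molarity uses a per-hydroxyl formula mass of 17.007 g/mol.

## In-line monitoring by PCA

The in-line stage mirrors standard chemometric practice for batch
reaction monitoring:

1. **Region selection** (`select_region()`): the default 600–800 nm
   window drops the short-wavelength region, where the probe signal is
   markedly noisier (the instrument acquires 342–825 nm).
2. **Mean-centering and PCA** (`mean_center()`, `fit_pca()`): singular
   value decomposition of the centered matrix $X = TP^\top + E$. Three
   components are computed by default — the reaction signal has been
   observed on PC1 or PC2 depending on conditions, and one spare
   accommodates a drift component. Loadings follow the
   largest-magnitude-entry-positive sign convention (component signs
   are otherwise arbitrary; the calibration is sign-invariant anyway).
3. **Disturbance masking** (`mask_disturbances()`): withdrawing an
   off-line sample perturbs the probe momentarily; acquisitions within
   2 min after each sampling event are excluded by default.
4. **Component selection** (`select_monitoring_pc()`): the component
   (among the first three) whose score correlates most strongly, in
   absolute value, with the reference $[POH]$ decay. Automating what is
   otherwise a per-run visual judgement keeps pipelines reproducible; a
   manual `component` override exists.
5. **Calibration** (`calibrate_scores()`): OLS of the modelled $[POH]$
   (the fitted kinetic decay evaluated at every retained acquisition
   time, linearly interpolated — trajectories are smooth and densely
   simulable, so interpolation error is negligible) on the score.
   Regressing concentration on score, rather than the reverse, makes
   the calibration directly predictive; $R^2$ is identical either way
   for simple regression. The first 15 min are excluded by default
   (configurable), because the off-line-anchored reference is least
   reliable there. Hourly off-line points can be used as the reference
   instead by passing a trajectory containing only those points.

## The synthetic-data generator

`generate_inline_spectra()` builds $A(\lambda, t) = \sum_c
\varepsilon_c(\lambda)\,C_c(t) + \mathrm{baseline} + \mathrm{spikes} +
\mathrm{noise}$ from a three-chromophore latent model: a
reactant-linked band driven by $[POH]$, a product-linked band driven by
the extent, and a slowly drifting medium component. The identities of
the chromophores behind the real 600–800 nm signal are unknown, so the
defaults are deliberately neutral Gaussians with no chemical claim
attached. The noise model defaults encode the qualitative structure of
the real data at desk scale: iid noise sd 0.002 AU above 600 nm and
0.02 AU below; a sinusoidal flat baseline drift of 0.005 AU with 8 h
period; 0.05 AU spikes lasting 2 min at each hourly sampling event
(true spike shapes are unknown; these are documented placeholders); and
for the off-line assays, sd 0.005 mol/L, a 0.25 h analysis delay, and
duplicate samples per hour. Acquisition geometry follows the
instrument: two spectra per minute, 342–825 nm at 0.24 nm (2013
points); `instrument_grid(coarse = TRUE)` gives a 2.4 nm grid for fast
runs.

What the generator does *not* emulate: probe optics and radiative
transfer, wavelength-correlated (pink) noise, temperature-dependent
baseline chemistry, and non-second-order late-stage kinetics. Passing
tests on synthetic data therefore demonstrate the correctness and
internal consistency of the algorithms under the stated statistical
structure — not that a particular real instrument will reach any given
$R^2$.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → fit-kinetics → monitor → calibrate
and writes every intermediate plus a JSON report. All randomness
derives from one master seed through stage-name-keyed substreams, so a
rerun of the same config is byte-identical. The built-in `sls60` and
`hls50` scenarios carry the studied parameter sets (softwood at 60 °C:
$k_1 = 1.53$, 71 % non-reactive, $[F]_0 = 0.59$, $[POH]_0 = 0.36$;
hardwood at 50 °C: $k_1 = 2.02$, $k_2 = 0.06$, 86 % non-reactive,
$[F]_0 = 0.79$, $[POH]_0 = 0.38$). In these scenarios the off-line
series is generated *clean* (no noise, no delay): the pipeline's role
there is self-consistency — recovering the scenario's parameters and
calibrating the monitor against them — while the in-line spectra keep
the full noise model. Noisy off-line studies are run by overriding the
`noise` config block.

```{r pipeline}
rep <- run_pipeline(pipeline_config("sls60", seed = 1))
rep
```

Problem sizes used throughout the package's own checks are desk-scale
by design: the coarse 202-point wavelength grid, 601 acquisitions, 6
hourly assay times in duplicate, and 100-replicate noise studies. They
were chosen as the smallest sizes at which every stage's behaviour is
exercised with comfortable statistical margins.

## Numerical choices and edge cases

* Closed form versus integrator: exact solution whenever $k_2 = 0$;
  lsoda otherwise, with concentrations clipped at zero only below
  $10^{-7}$ (larger undershoot raises an internal error).
* Equal-concentration degeneracy: handled by a dedicated branch at
  $10^{-10}$ relative difference.
* PCA on rank-deficient matrices: trailing components are flagged
  `zero_variance` rather than dropped.
* Peak finding at a window edge is reported `found = FALSE` instead of
  returning an extrapolated height.
* Negative predicted concentrations and negative type III+IV contents
  are floored at zero with warnings.
* Ties in component selection and in the multi-start fit are broken
  deterministically (lower index, smaller $k_1$).

## Known limitations

* The kinetic model ignores late-stage deviations from second-order
  behaviour that real runs can show; residual structure at long times
  is expected there.
* The score–concentration map is a single-component affine calibration;
  multi-component (PLS-style) regression is out of scope.
* The ionization-difference coefficients are placeholders pending
  instrument calibration, as discussed above.
* No Arrhenius extrapolation across temperatures is offered.
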