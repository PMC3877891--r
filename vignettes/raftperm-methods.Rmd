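---
title: "raftperm: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{raftperm: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(raftperm)
```

`raftperm` implements the quantitative toolbox for studying a
membrane-permeabilizing, raft-targeting drug: fluctuation microscopy of
raft-marker clustering, membrane image quantification, dose–response
analysis, a mechanistic pore-formation model, binding kinetics, and
membrane-probe polarimetry. This vignette records the models and the
numerically consequential decisions; it states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## 1. Number & Brightness analysis

N&B treats a time series of photon-count frames pixel by pixel. For photon
counts $k$ with temporal mean $\langle k\rangle$ and variance $\sigma^2$,
the apparent brightness is

$$B = \frac{\sigma^2}{\langle k\rangle},$$

and the molecular brightness is $\varepsilon = B - 1$ (photon-counting
convention: detector shot noise alone gives $B = 1$, so $\varepsilon$ is
the excess — the photons contributed per independently diffusing unit per
pixel dwell). A dimer doubles $\varepsilon$; an immobile or background
pixel has $\varepsilon = 0$. When a monomer reference brightness is
supplied, `molecular_brightness()` also reports the oligomerization ratio
$\varepsilon/\varepsilon_{\mathrm{ref}}$.

Conventions and choices:

* **Population variance** (denominator $T$). At a typical $T = 100$ the
  difference from the sample variance is 1% of $B$; at the $T$ used by the
  oracle tests it is negligible.
* **Integer-shift registration.** Frames are aligned to the first frame by
  the integer translation maximizing the mean-subtracted cyclic
  cross-correlation (computed by FFT). Sub-pixel interpolation is
  deliberately avoided: it would mix neighbouring counts and destroy the
  Poisson statistics that the $B = 1$ baseline relies on. Pixels exposed at
  the frame edge become `NA` and are excluded from all moments. A
  correlation peak must stand at least `min_peak_z = 5` robust standard
  deviations above the correlation surface; otherwise the frame has no
  registration signal (e.g. a spatially homogeneous field) and keeps the
  identity shift, flagged. Registration is idempotent: a second pass finds
  zero shifts.
* **Analysis region.** By default the central 128×128 px of the field is
  analyzed, avoiding scanner-turnaround artifacts near frame borders.
* **Mean floor.** Pixels with mean count ≤ 0.1 are excluded from brightness
  maps; the ratio $\sigma^2/\langle k\rangle$ at near-empty pixels is
  noise-dominated and uninformative.
* **Pooled estimator.** The region summary uses both a robust centre
  (median, MAD) and the pooled estimate
  $\hat\varepsilon = \sum(\sigma^2_i - \langle k\rangle_i)/\sum\langle
  k\rangle_i$, which is the minimum-variance combination for a
  homogeneous region and is what the oracle tests check.

### Stack quality control

Two acquisition-health rules are applied by `qc_stack()`:

1. **Mean decay.** The relative drop between the mean of the first and last
   deciles of frame means must not exceed 10% (stage drift or
   photobleaching). A 20% linear bleach fails this rule by construction.
2. **Convergence.** "The per-pixel variance must converge with stack size"
   is operationalized as: the spatial average of
   $(\bar k_n - \bar k_T)^2$, where $\bar k_n$ is the cumulative mean over
   the first $n$ frames, must decay with log–log slope ≤ −0.5 over
   log-spaced prefixes up to $T/2$ (a stationary signal gives ≈ −1, since
   the estimator variance scales as $1/n$; trends and mid-acquisition step
   changes plateau near 0). The prefix schedule and the −0.5 threshold are
   configurable; stacks shorter than 20 frames are rejected as not
   evaluable (`short_stack`).

   The convergence statistic detects nonstationarity *above the shot-noise
   floor*: a step change must displace the cumulative mean by more than
   roughly $\sigma/\sqrt{n}$ to register. The QC fixtures therefore use
   realistically bright stacks (mean count ≈ 4); a very dim stack with the
   same relative step passes undetected, which is a physical detection
   limit, not a bug.

## 2. Synthetic N&B stacks

`gen_nb_stack()` uses the *fast-diffusion limit*: the emitter occupancy $N$
of each pixel is redrawn every frame as Poisson with mean $\bar n$, and
detected counts are Poisson with mean $N\varepsilon + b$. By the law of
total variance the exact expected brightness is

$$B = 1 + \frac{\bar n\,\varepsilon^2}{\bar n\,\varepsilon + b},$$

which reduces to $B = 1 + \varepsilon$ at zero background — the analytic
oracle used throughout. This choice trades realism (no frame-to-frame
correlation, no PSF blur — both would break the closed form) for a ground
truth that is exact rather than itself simulated. Bleaching is a
multiplicative linear schedule on the expected counts (1 down to
$1-\text{bleach}$); drift is a cumulative integer shift of the occupancy
pattern. A non-uniform `occupancy_map` is what makes drift observable; the
spatially homogeneous default is stationary by construction.

## 3. Image quantification

* **Seeded watershed.** The relief is the gradient magnitude of the
  Gaussian-smoothed image (σ = 1 px default; the relief choice is not
  dictated by the measurement and is configurable). Meyer's priority-flood
  assigns every pixel to the seed basin that reaches it first (FIFO
  tie-break, so flooding is deterministic; on perfectly flat relief the
  fronts meet near the equidistant line between seeds, up to the
  8-connected grid metric). The membrane mask is every pixel within
  `ridge_width` (default 3 px, Euclidean) of a boundary separating a
  cell-labelled basin from a non-cell basin.
* **Spot counting** runs a fixed operator sequence: Gaussian smoothing →
  division by the image maximum → white top-hat with a disk (radius must
  exceed the smoothing σ; removes structures larger than the spot scale) →
  extended-maxima transform (depth `h_maxima` on the normalized scale,
  default 0.1) → hole filling → one point per connected maxima component
  (centroid; ties round toward the smaller index). Division by the maximum
  makes the count invariant under positive rescaling. The defaults
  (σ = 1.5, top-hat radius 8, h = 0.1) are calibrated on the synthetic
  fixtures — spots of σ = 2 px separated by ≥ 4σ — not on any particular
  microscope's images.
* **Coordinates are 1-based (row, column)** throughout, the native R
  convention for matrices; masks, label maps and seed lists share it.
* **PI positivity** thresholds per-cell intensities either at a fixed value
  or by Otsu's method on log intensities (default), which suits the
  bimodal live/dead mixture and is reproducible.

## 4. Hill dose–response fitting

`fit_hill()` fits
$R(c) = \text{bottom} + (\text{top}-\text{bottom})\,c^n/(c^n +
\mathrm{EC50}^n)$ by least squares. Two structural choices make the fit
fast and reliable:

* the search runs on $(\log_{10}\mathrm{EC50}, \log n)$ only — for any
  candidate pair the two plateaus enter the model linearly and are solved
  by linear least squares (respecting fixed-plateau constraints such as
  `bottom = 0, top = 1` for fraction data);
* five log-spaced EC50 starts across the concentration range (Hill
  coefficient starting at 1) followed by a derivative-free polish guard
  against local minima. Noiseless data are recovered to ~1e-14 relative.

Bounds: $n \in [0.1, 10]$, EC50 within $[\min(c)/100, 100\max(c)]$.
Fitting is unweighted in plain response space. Decreasing curves swap the
plateau roles so `bottom ≤ top` always refers to response values. Data in
which no concentration leaves the plateau (span below 5% of the response
magnitude) raise an *unidentifiable EC50* error rather than returning an
arbitrary number. `ic50_from_viability()` converts dual-wavelength
absorbance plates (signal = A450 − A620, normalized by untreated controls,
non-positive control wells excluded) before fitting.

Cooperativity classification in `compare_binding_killing()` uses
n ≤ 1.5 → non-cooperative, n ≥ 2 → cooperative; the gap is reported as
"intermediate" rather than forced into either class.

## 5. The oligomer-threshold permeabilization model

The mechanistic chain is deliberately minimal:

1. **Binding** is Langmuir: $b(c) = S\,c/(c + K_d)$ — non-cooperative by
   construction; a Hill fit of any sampled binding curve returns $n = 1$.
2. **Oligomerization** is a weak-association mass-action closure:
   $\rho_m = k_{\mathrm{olig}}\, b^m$ with integer order $m$ (default 4,
   alternative 3).
3. **Killing** occurs when $\rho_m$ crosses a per-cell threshold, log-normal
   across the population (median $\theta$, log-spread $\sigma_\theta$):
   $$P(c) = \Phi\!\left(\frac{\ln\rho_m(c) - \ln\theta}{\sigma_\theta}\right).$$
   The log-normal choice encodes positivity and multiplicative cell-to-cell
   variability; $\sigma_\theta = 0$ degenerates to a sharp step.

The exact functional forms of the original supplementary treatment were not
available; this closure is the smallest model consistent with every
statement in the main text, and no claim is made that it matches the
authors' equations term by term.

Calibration is closed-form: $P = 0.5$ exactly where $\rho_m = \theta$, so
`calibrate_threshold()` inverts to
$\theta = k_{\mathrm{olig}}\,b(\mathrm{IC50})^m$ independent of
$\sigma_\theta$. The shipped demo configuration (`paper_regime.json`) sets
$K_d = 5.1$ µM, $m = 4$, target IC50 = 10.2 µM and $\sigma_\theta = 0.6$;
the spread is the one free calibration constant and was chosen once so the
apparent killing Hill coefficient lands in the 3–4 band characteristic of
the mechanism (the local log-slope of $\ln\rho_m$ at the IC50 is
$m K_d/(c+K_d) = 4/3$, and a probit transition of that slope with
$\sigma_\theta = 0.6$ fits an apparent $n \approx 3.6$).

Two subtleties worth knowing:

* **Resistant fractions.** Because binding saturates at $S$, the killing
  probability saturates at
  $P(\infty) = \Phi(m\ln(S/b_c)/\sigma_\theta)$ with
  $b_c = (\theta/k_{\mathrm{olig}})^{1/m}$. If the calibrated IC50 sits at
  two thirds of saturation (the demo regime) and $m = 1$, $P$ never reaches
  0.95 — the transition cannot be spanned and `apparent_hill_of_killing()`
  refuses the grid. Sweeps across $m$ therefore calibrate at lower
  occupancy (e.g. IC50 = $K_d/2$, one third of saturation).
* **Site-density sensitivity.** $P = 0.5$ at $b = b_c$ gives the exact
  relation $\mathrm{IC50}(S) = K_d\,b_c/(S - b_c)$: monotone decreasing in
  $S$, diverging as $S \to b_c$ (the critical density below which the line
  is flagged resistant/no-kill), and scaling as $1/S$ far above it. The
  *directional* prediction — a twofold site loss is nearly harmless far
  above the critical level (bounded, ≈2× in IC50) but catastrophic near it
  (unbounded) — holds and is asserted in the tests. The stronger
  quantitative reading that the far-from-critical change is below 15%
  is not attainable in this model family: $|\mathrm d\ln\mathrm{IC50}/
  \mathrm d\ln S| \ge 1/\ln 10 \approx 0.43$ at $S = 10\times$ critical for
  every closure of the form $\rho \propto S^a f(c)^m$, so halving $S$
  always raises the IC50 by at least ~35%. The corresponding acceptance
  assertion is left failing on purpose rather than silently weakened.

`ic50_of_sites()` finds $P(c) = 0.5$ by bisection on $\log c$ (relative
tolerance 1e-6); `permeabilization_probability_mc()` provides the
independent Monte-Carlo route (sampled log-normal thresholds) that the
closed form is verified against.

## 6. Uptake kinetics and the initial-slope estimator

The two-compartment model is irreversible: free drug at fixed concentration
$c$ (non-depleting reservoir) binds at rate $a = k_{\mathrm{on}} c$ and
bound drug internalizes at first order $k_{\mathrm{int}}$, with no
dissociation term — internalization dominates on the measurement time
scale, so $k_{\mathrm{off}}$ is omitted. With $\kappa = a + k_{\mathrm{int}}$:

$$B(t) = \frac{aS}{\kappa}\left(1 - e^{-\kappa t}\right),\qquad
I(t) = k_{\mathrm{int}}\int_0^t B,\qquad
F(t) = \alpha\,(B + I) + \text{bg}.$$

The closed form is verified against an RK4 integration in the tests. The
initial slope of $F$ is $\alpha\,k_{\mathrm{on}} c S$ — proportional to the
site amount $S$ — and `initial_slope()` estimates it by ordinary least
squares over a 30 s default window (least squares rather than two-point for
noise robustness). The estimator bias is below 5% whenever
$\kappa\,\text{window} \le 0.1$ and grows with the window as curvature sets
in. `fold_reduction()` of two slopes cancels $\alpha$ and the background,
making the binding-loss readout instrument-gain independent.

## 7. Membrane probes

The anisotropy and GP formulas are textbook definitions matching the
symbol conventions of the underlying measurements exactly:
$r = (I_{vv} - G I_{vh})/(I_{vv} + 2 G I_{vh})$ and
$GP = (I_{blue} - I_{red})/(I_{blue} + I_{red})$. The G-factor is accepted
as a measured input and never computed. `compare_conditions()` reports
mean ± SEM per condition and delegates the two-condition comparison to
Welch's t-test; no polarimetry physics beyond the ratios is modelled.

## 8. Correlation confidence intervals

`correlation_with_ci()` applies the Fisher transform
$z = \operatorname{atanh} r$ with standard error $1/\sqrt{n-3}$ to both
Pearson and Spearman coefficients (mid-rank ties). The classical Spearman
variance inflations (1.03, 1.06) are available but off by default, since
the plain transform is what the analyses this package mirrors applied to
both methods. $|r| = 1$ yields a degeneracy flag instead of an interval.
Empirical coverage at $\rho = -0.9$, $n = 21$ is within 95% ± 2% over
5000 simulations (tested).

## 9. What the synthetic generators do and do not establish

The generators reproduce the *statistical structure* the estimators rely
on: Poisson photon statistics over fluctuating occupancy, rim-shaped
membrane geometry with diffuse background, well-separated Gaussian spots on
smooth ramps with oversized distractor objects, model-mean dose–response
tables with truncated Gaussian replicate noise, closed-form uptake traces,
and bivariate-normal cell-line panels. They do **not** emulate PSF blur or
pixel cross-correlation, detector afterpulsing or analog-gain calibration,
chromatic aberration, 3-D geometry, irregular cell shapes, or heavy-tailed
biological outliers. A green test therefore establishes estimator
correctness under the stated noise model — not robustness to every
real-microscope artifact. Replicate noise models for dose–response and
uptake data are declared choices (additive Gaussian, truncated to the valid
range), not transcriptions of any published noise analysis.

## 10. File formats

All interchange formats are plain text: ASCII PGM (P2) for 2-D images, a
whitespace matrix plus JSON sidecar for image stacks, CSV for tables, JSON
for configurations, ground truth (`*.truth.json`) and results. Binary
microscope formats are out of scope for this package's dependency set.

## 11. Known limitations

* Registration is integer-pixel only; sub-pixel drift below the peak
  significance threshold is invisible.
* The convergence QC statistic cannot detect nonstationarity buried under
  shot noise (Section 1).
* The oligomer model is an equilibrium closure: no kinetic pore model, no
  spatial raft-clustering stochastics.
* Two-channel (cross) N&B, Manders/Costes colocalization, unseeded
  segmentation, and Bayesian dose–response modelling are out of scope.
* Spearman confidence intervals use the Fisher approximation, which is
  known to be slightly liberal for $|\rho| \gtrsim 0.9$ at small $n$.
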